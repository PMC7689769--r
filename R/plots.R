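#' Plot the central slice of a field map
#'
#' Tiles the main-field component over the slice of points closest to the
#' given plane.
#'
#' @param object a `field_map`.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.field_map <- function(object, plane = "yz", ...) {
  third <- setdiff(c("x", "y", "z"), strsplit(plane, "")[[1]])
  df <- as_tibble(object)
  cut <- df[[third]][which.min(abs(df[[third]]))]
  df <- df[abs(df[[third]] - cut) < 1e-9, ]
  ax <- strsplit(plane, "")[[1]]
  ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                   fill = .data$b0 * 1e3)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "B0 (mT)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(ax[1], "(m)"), y = paste(ax[2], "(m)"))
}

#' Plot gradient coil wires unrolled onto the former surface
#'
#' @param object a [wire_set()].
#' @param ... unused.
#' @return a ggplot of the azimuth-axial wire layout, colored by path.
#' @export
autoplot.wire_set <- function(object, ...) {
  p <- object$paths |>
    mutate(theta = atan2(.data$y, .data$z))
  ggplot2::ggplot(p, ggplot2::aes(.data$theta, .data$x,
                                  group = .data$path_id,
                                  color = factor(.data$path_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::labs(x = "azimuth (rad, from B0 axis)", y = "axial position (m)")
}

#' Plot the GA convergence trace
#'
#' @param object a `ring_optim` or `shim_optim`.
#' @param ... unused.
#' @return a ggplot of best and mean fitness per generation.
#' @export
autoplot.ring_optim <- function(object, ...) {
  tr <- tidy(object) |>
    tidyr::pivot_longer(c("best", "mean"), names_to = "which",
                        values_to = "ppm")
  ggplot2::ggplot(tr, ggplot2::aes(.data$generation, .data$ppm,
                                   linetype = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "homogeneity (ppm)")
}

#' @rdname autoplot.ring_optim
#' @export
autoplot.shim_optim <- autoplot.ring_optim

#' Plot the echo assignment of an encode schedule
#'
#' @param object an `encode_schedule`.
#' @param ... unused.
#' @return a ggplot tiling echo index over the phase-encode plane.
#' @export
autoplot.encode_schedule <- function(object, ...) {
  ggplot2::ggplot(object$entries,
                  ggplot2::aes(.data$k1, .data$k2, fill = .data$echo)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "echo") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "phase 1 index", y = "phase 2 index")
}

#' Plot the central slice of an image volume or phantom
#'
#' @param object an `image_volume` or `mri_phantom`.
#' @param slice z-slice index; defaults to the central slice.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.image_volume <- function(object, slice = NULL, ...) {
  v <- object$voxels
  slice <- slice %||% (floor(dim(v)[3] / 2) + 1L)
  df <- expand.grid(
    x = .centered_coords(dim(v)[1], object$spacing[1]),
    y = .centered_coords(dim(v)[2], object$spacing[2])
  )
  df$value <- as.vector(v[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "signal") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' @rdname autoplot.image_volume
#' @export
autoplot.mri_phantom <- function(object, slice = NULL, ...) {
  autoplot.image_volume(
    image_volume(object$rho, object$spacing, "phantom proton density"),
    slice = slice, ...)
}
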