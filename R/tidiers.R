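#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the generation trace of a ring-diameter optimization
#'
#' @param x a `ring_optim` from [optimize_ring_diameters()].
#' @param ... unused.
#' @return tibble `generation, best, mean` (ppm).
#' @export
tidy.ring_optim <- function(x, ...) x$trace

#' @rdname tidy.ring_optim
#' @return `glance()`: one-row tibble with the final homogeneity (`ppm`),
#'   mean DSV field (`mean_b0_mT`) and ring count.
#' @export
glance.ring_optim <- function(x, ...) {
  tibble(ppm = x$ppm, mean_b0_mT = x$mean_b0 * 1e3,
         n_rings = nrow(x$design$rings))
}

#' Tidy the generation trace of a shim optimization
#'
#' @param x a `shim_optim` from [optimize_shim()].
#' @param ... unused.
#' @export
tidy.shim_optim <- function(x, ...) x$trace

#' @rdname tidy.shim_optim
#' @export
glance.shim_optim <- function(x, ...) {
  tibble(ppm = x$ppm, ppm_unshimmed = x$ppm_unshimmed,
         improvement = x$ppm_unshimmed / x$ppm,
         n_magnets = sum(x$grid$state != 0))
}

#' Tidy a gradient performance report
#'
#' @param x a `gradient_performance`.
#' @param ... unused.
#' @return the underlying field map with the deviation from the ideal ramp.
#' @export
tidy.gradient_performance <- function(x, ...) {
  fm <- x$field_map
  ic <- match(x$axis, c("x", "y", "z"))
  G0 <- x$efficiency / 1e3
  u <- .points_matrix(fm)[, ic]
  mutate(as_tibble(fm),
         deviation_pct = abs(.data$Bz - G0 * u) / abs(G0 * x$fov / 2) * 100)
}

#' @rdname tidy.gradient_performance
#' @export
glance.gradient_performance <- function(x, ...) {
  tibble(axis = x$axis, efficiency_mT_m_A = x$efficiency,
         nonlinearity_pct = x$nonlinearity_max, fov_m = x$fov,
         resistance_ohm = x$resistance_estimate)
}

#' Tidy an encode schedule
#'
#' @param x an `encode_schedule`.
#' @param ... unused.
#' @export
tidy.encode_schedule <- function(x, ...) x$entries

#' @rdname tidy.encode_schedule
#' @export
glance.encode_schedule <- function(x, ...) {
  tibble(shots = x$shots, effective_te_ms = x$effective_te,
         n_encodes = nrow(x$entries), etl = x$params$etl,
         scan_time_s = scan_time(x$params))
}

#' Tidy distortion metrics
#'
#' @param x a `distortion_metrics`.
#' @param ... unused.
#' @export
tidy.distortion_metrics <- function(x, ...) x$per_blob

#' @rdname tidy.distortion_metrics
#' @export
glance.distortion_metrics <- function(x, ...) {
  tibble(rms_mm = x$rms_mm, n_detected = x$n_detected,
         n_reference = x$n_reference)
}

#' Tidy an image volume into voxel records
#'
#' @param x an `image_volume`.
#' @param ... unused.
#' @return tibble `x, y, z` (mm), `value`.
#' @export
tidy.image_volume <- function(x, ...) {
  bind_cols(voxel_coords(x), tibble(value = as.vector(x$voxels)))
}

#' Tidy k-space samples (masked lines only)
#'
#' @param x a `kspace_data`.
#' @param ... unused.
#' @return tibble `kx_idx, k1, k2, re, im, mod`.
#' @export
tidy.kspace_data <- function(x, ...) {
  d <- dim(x$samples)
  e <- x$schedule$entries
  purrr::map_dfr(seq_len(nrow(e)), function(l) {
    s <- x$samples[, e$k1[l] + floor(d[2] / 2) + 1L,
                   e$k2[l] + floor(d[3] / 2) + 1L]
    tibble(kx_idx = .centered_coords(d[1], 1), k1 = e$k1[l], k2 = e$k2[l],
           re = Re(s), im = Im(s), mod = Mod(s))
  })
}
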