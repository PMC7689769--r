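#' Build a table of permanent-magnet elements
#'
#' A magnet element is a cube (or other small block) of permanently
#' magnetized material reduced to a point dipole at its center, with dipole
#' moment `m = remanence * volume / mu0` along `moment_dir`. This is the
#' elementary source for all Halbach-array field computations.
#'
#' @param center numeric matrix (n x 3) or data frame of element centers (m).
#' @param moment_dir numeric matrix (n x 3) of magnetization directions;
#'   rows must be unit vectors (renormalized if within 1e-6 of unit length).
#' @param remanence remanent flux density Br of the material (T). Recycled.
#' @param volume element volume (m^3). Recycled.
#' @return a tibble with columns `x, y, z` (center), `mx, my, mz` (unit
#'   moment direction), `remanence`, `volume`.
#' @examples
#' magnet_elements(c(0, 0, 0), c(0, 0, 1), remanence = 1.42, volume = 0.012^3)
#' @export
magnet_elements <- function(center, moment_dir, remanence, volume) {
  center <- .as_matrix3(center, "center")
  moment_dir <- .as_matrix3(moment_dir, "moment_dir")
  if (nrow(center) != nrow(moment_dir)) {
    abort("`center` and `moment_dir` must have the same number of rows.")
  }
  nrm <- sqrt(rowSums(moment_dir^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    abort("rows of `moment_dir` must be unit vectors (|dir| within 1e-6 of 1).")
  }
  moment_dir <- moment_dir / nrm
  if (any(remanence <= 0)) abort("`remanence` must be positive.")
  if (any(volume <= 0)) abort("`volume` must be positive.")
  tibble(
    x = center[, 1], y = center[, 2], z = center[, 3],
    mx = moment_dir[, 1], my = moment_dir[, 2], mz = moment_dir[, 3],
    remanence = rep_len(remanence, nrow(center)),
    volume = rep_len(volume, nrow(center))
  )
}

.as_matrix3 <- function(x, name) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  if (ncol(x) != 3) abort(sprintf("`%s` must have 3 columns.", name))
  storage.mode(x) <- "double"
  x
}

#' Cartesian evaluation grids and spherical sampling shells
#'
#' `grid_points()` builds a regular Cartesian lattice of evaluation points.
#' `dsv_points()` samples a diameter-of-spherical-volume (DSV) region with
#' concentric Fibonacci-spiral shells plus the center point -- a cheap,
#' rotation-fair deterministic sample used as the homogeneity objective grid.
#'
#' @param x,y,z numeric vectors of coordinates (m); the grid is their
#'   Cartesian product.
#' @return a tibble with columns `x, y, z` (m).
#' @examples
#' grid_points(seq(-0.1, 0.1, 0.05), 0, 0)
#' dsv_points(diameter = 0.2)
#' @export
grid_points <- function(x, y = x, z = x) {
  g <- expand.grid(x = x, y = y, z = z, KEEP.OUT.ATTRS = FALSE)
  as_tibble(g)
}

#' @rdname grid_points
#' @param diameter DSV diameter (m).
#' @param center 3-vector center of the sphere (m).
#' @param n_shells number of concentric shells.
#' @param n_per_shell points per shell (Fibonacci sphere).
#' @export
dsv_points <- function(diameter, center = c(0, 0, 0), n_shells = 11,
                       n_per_shell = 100) {
  stopifnot(diameter > 0, n_shells >= 1, n_per_shell >= 1)
  R <- diameter / 2
  shells <- lapply(seq_len(n_shells), function(k) {
    (R * k / n_shells) * .fibonacci_sphere(n_per_shell)
  })
  pts <- rbind(matrix(0, 1, 3), do.call(rbind, shells))
  tibble(
    x = pts[, 1] + center[1],
    y = pts[, 2] + center[2],
    z = pts[, 3] + center[3]
  )
}

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  polar <- acos(1 - 2 * i / n)
  azim <- pi * (1 + sqrt(5)) * i
  cbind(sin(polar) * cos(azim), sin(polar) * sin(azim), cos(polar))
}

#' Spherical (DSV) region descriptor
#'
#' @param diameter sphere diameter (m).
#' @param center 3-vector center (m).
#' @return a list of class `dsv_region` with the diameter, center and the
#'   default sample points from [dsv_points()].
#' @export
dsv_region <- function(diameter, center = c(0, 0, 0)) {
  structure(
    list(diameter = diameter, center = center,
         points = dsv_points(diameter, center)),
    class = "dsv_region"
  )
}

# field map container: a tibble x,y,z,Bx,By,Bz,b0 with the B0 axis recorded
new_field_map <- function(points, B, b0_axis = "z") {
  iax <- match(b0_axis, c("x", "y", "z"))
  if (is.na(iax)) abort("`b0_axis` must be one of \"x\", \"y\", \"z\".")
  out <- tibble(
    x = points[, 1], y = points[, 2], z = points[, 3],
    Bx = B[, 1], By = B[, 2], Bz = B[, 3], b0 = B[, iax]
  )
  attr(out, "b0_axis") <- b0_axis
  class(out) <- c("field_map", class(out))
  out
}

.points_matrix <- function(points) {
  if (is.data.frame(points)) {
    as.matrix(points[, c("x", "y", "z")])
  } else {
    .as_matrix3(points, "points")
  }
}

#' Magnetic field of point-dipole magnet elements
#'
#' Sums the point-dipole field
#' `B = (mu0 / 4 pi) (3 (m . rhat) rhat - m) / r^3` over all elements, with
#' `m = remanence * volume / mu0 * moment_dir`. Cube magnets a few
#' centimeters from the evaluation region are represented to sub-percent
#' accuracy by this approximation.
#'
#' @param elements tibble from [magnet_elements()].
#' @param points evaluation points: a tibble with `x, y, z` columns or an
#'   n x 3 matrix (m).
#' @param b0_axis which field component is the main (B0) field; `"z"` for the
#'   transverse-field Halbach convention used throughout.
#' @return a `field_map` tibble with columns `x, y, z, Bx, By, Bz, b0`.
#' @examples
#' el <- magnet_elements(c(0, 0, 0), c(0, 0, 1), 1.42, 0.012^3)
#' dipole_field(el, grid_points(0, 0, c(0.1, 0.2)))
#' @export
dipole_field <- function(elements, points, b0_axis = "z") {
  pts <- .points_matrix(points)
  cen <- as.matrix(elements[, c("x", "y", "z")])
  m0 <- elements$remanence * elements$volume / MU0
  mom <- as.matrix(elements[, c("mx", "my", "mz")]) * m0
  half_size <- (elements$volume)^(1 / 3) / 2
  B <- .dipole_field_matrix(cen, mom, pts, min_dist = half_size)
  new_field_map(pts, B, b0_axis)
}

# cen: E x 3, mom: E x 3 dipole moments (A m^2), pts: P x 3.
# min_dist: per-element singularity guard (error if any pair closer).
.dipole_field_matrix <- function(cen, mom, pts, min_dist = NULL) {
  P <- nrow(pts)
  E <- nrow(cen)
  B <- matrix(0, P, 3)
  if (E == 0L) return(B)
  chunk <- max(1L, floor(4e6 / P))
  for (s in seq(1, E, by = chunk)) {
    e <- seq(s, min(s + chunk - 1L, E))
    dx <- outer(pts[, 1], cen[e, 1], "-")
    dy <- outer(pts[, 2], cen[e, 2], "-")
    dz <- outer(pts[, 3], cen[e, 3], "-")
    r2 <- dx * dx + dy * dy + dz * dz
    if (!is.null(min_dist)) {
      bad <- which(r2 < matrix(min_dist[e]^2, P, length(e), byrow = TRUE),
                   arr.ind = TRUE)
      if (nrow(bad)) {
        abort(sprintf(
          "evaluation point %d lies inside/too near magnet element %d (distance %.2g m).",
          bad[1, 1], e[bad[1, 2]], sqrt(r2[bad[1, 1], bad[1, 2]])
        ))
      }
    }
    ir3 <- r2^(-1.5)
    ir5 <- ir3 / r2
    md <- sweep(dx, 2, mom[e, 1], "*") + sweep(dy, 2, mom[e, 2], "*") +
      sweep(dz, 2, mom[e, 3], "*")
    ne <- length(e)
    B[, 1] <- B[, 1] + 1e-7 * rowSums(3 * md * dx * ir5 -
      matrix(mom[e, 1], P, ne, byrow = TRUE) * ir3)
    B[, 2] <- B[, 2] + 1e-7 * rowSums(3 * md * dy * ir5 -
      matrix(mom[e, 2], P, ne, byrow = TRUE) * ir3)
    B[, 3] <- B[, 3] + 1e-7 * rowSums(3 * md * dz * ir5 -
      matrix(mom[e, 3], P, ne, byrow = TRUE) * ir3)
  }
  B
}

#' Magnetic field of a wire set by Biot-Savart integration
#'
#' Each wire path is treated as a polyline of straight segments carrying the
#' common current; the exact finite-segment Biot-Savart expression is summed
#' over all segments. The result converges to the smooth-curve field as the
#' polylines are refined.
#'
#' @param wires a [wire_set()] object.
#' @param points evaluation points (tibble with `x, y, z` or n x 3 matrix, m).
#' @param current overrides the wire-set current (A) when given.
#' @param b0_axis main-field axis for the `b0` column.
#' @return a `field_map` tibble.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)
#' loop <- wire_set(tibble::tibble(path_id = 1, x = 0, y = 0.1 * cos(th),
#'                                 z = 0.1 * sin(th)), current = 1)
#' biot_savart(loop, grid_points(0, 0, 0))
#' @export
biot_savart <- function(wires, points, current = NULL, b0_axis = "z") {
  stopifnot(inherits(wires, "wire_set"))
  pts <- .points_matrix(points)
  I <- if (is.null(current)) wires$current else current
  if (!is.finite(I)) abort("`current` must be finite.")
  seg <- .wire_segments(wires)
  B <- .biot_savart_matrix(seg$a, seg$b, pts) * I
  new_field_map(pts, B, b0_axis)
}

.wire_segments <- function(wires) {
  p <- wires$paths
  a <- NULL
  b <- NULL
  for (id in unique(p$path_id)) {
    xyz <- as.matrix(p[p$path_id == id, c("x", "y", "z")])
    if (nrow(xyz) < 2) abort(sprintf("wire path %s has fewer than 2 points.", id))
    a <- rbind(a, xyz[-nrow(xyz), , drop = FALSE])
    b <- rbind(b, xyz[-1, , drop = FALSE])
  }
  keep <- rowSums((a - b)^2) > 0
  list(a = a[keep, , drop = FALSE], b = b[keep, , drop = FALSE])
}

# field per unit current of straight segments a->b at pts; dl x rhat convention
.biot_savart_matrix <- function(a, b, pts) {
  P <- nrow(pts)
  B <- matrix(0, P, 3)
  S <- nrow(a)
  chunk <- max(1L, floor(2e6 / P))
  for (s0 in seq(1, S, by = chunk)) {
    idx <- seq(s0, min(s0 + chunk - 1L, S))
    for (k in idx) {
      r1 <- cbind(pts[, 1] - a[k, 1], pts[, 2] - a[k, 2], pts[, 3] - a[k, 3])
      r2 <- cbind(pts[, 1] - b[k, 1], pts[, 2] - b[k, 2], pts[, 3] - b[k, 3])
      n1 <- sqrt(rowSums(r1^2))
      n2 <- sqrt(rowSums(r2^2))
      d <- b[k, ] - a[k, ]
      denom <- n1 * n2 * (n1 * n2 + rowSums(r1 * r2))
      if (any(denom < 1e-18)) {
        abort(sprintf("evaluation point %d lies on wire segment %d.",
                      which(denom < 1e-18)[1], k))
      }
      f <- 1e-7 * (n1 + n2) / denom
      B[, 1] <- B[, 1] + (d[2] * r1[, 3] - d[3] * r1[, 2]) * f
      B[, 2] <- B[, 2] + (d[3] * r1[, 1] - d[1] * r1[, 3]) * f
      B[, 3] <- B[, 3] + (d[1] * r1[, 2] - d[2] * r1[, 1]) * f
    }
  }
  B
}

#' Field homogeneity in parts per million
#'
#' The default metric is the peak-to-peak convention
#' `(max - min) / mean * 1e6` of the main-field component over the region
#' samples; `method = "rms"` gives the RMS variant
#' `sd / mean * 1e6`.
#'
#' @param field a `field_map` tibble (needs the `b0` column).
#' @param region optional [dsv_region()]; when given, only field points
#'   inside the sphere are used.
#' @param method `"peak_to_peak"` (default) or `"rms"`.
#' @return homogeneity in ppm (dimensionless).
#' @export
homogeneity_ppm <- function(field, region = NULL,
                            method = c("peak_to_peak", "rms")) {
  method <- match.arg(method)
  b0 <- field$b0
  if (!is.null(region)) {
    stopifnot(inherits(region, "dsv_region"))
    r <- sqrt((field$x - region$center[1])^2 + (field$y - region$center[2])^2 +
                (field$z - region$center[3])^2)
    b0 <- b0[r <= region$diameter / 2 + 1e-12]
  }
  if (length(b0) < 2) abort("region must contain at least 2 field samples.")
  mu <- mean(b0)
  if (mu <= 0) {
    abort("mean main-field component is <= 0; is `b0_axis` configured correctly?")
  }
  if (method == "peak_to_peak") {
    (max(b0) - min(b0)) / mu * 1e6
  } else {
    sqrt(mean((b0 - mu)^2)) / mu * 1e6
  }
}

#' Larmor frequency of protons
#'
#' `f = (gamma / 2 pi) B0` with `gamma / 2 pi = 42.5774785 MHz/T`; at the
#' 50 mT design field this is about 2.13 MHz.
#'
#' @param b0 main field (T), non-negative.
#' @return frequency (Hz).
#' @export
larmor_frequency <- function(b0) {
  if (any(b0 < 0)) abort("`b0` must be non-negative.")
  GAMMA_HZ_PER_T * b0
}

#' Thermal drift sensitivity of the resonance frequency
#'
#' NdFeB remanence decreases with temperature (typically ~0.1-0.12 %/degC),
#' so the resonance frequency drifts by
#' `larmor_frequency(B0) * |tempco|` per degree Celsius -- about 2.5 kHz/degC
#' at 50 mT.
#'
#' @param b0 main field (T).
#' @param tempco fractional remanence change per degree Celsius
#'   (default 0.12 %/degC = 0.0012); magnitude must be below 0.01.
#' @return sensitivity (Hz per degC).
#' @export
thermal_drift_sensitivity <- function(b0, tempco = 0.0012) {
  if (any(abs(tempco) >= 0.01)) {
    abort("`tempco` magnitude must be < 0.01 (a fraction per degC, not percent).")
  }
  larmor_frequency(b0) * abs(tempco)
}

#' Johnson (thermal) noise voltage density
#'
#' `sqrt(4 kB T R)` reported in nV per sqrt(Hz); 50 ohm at 290 K gives the
#' familiar 0.9 nV/sqrt(Hz) receiver noise floor.
#'
#' @param resistance source resistance (ohm), non-negative.
#' @param temperature absolute temperature (K), positive.
#' @return noise density (nV / sqrt(Hz)).
#' @export
johnson_noise_density <- function(resistance, temperature = T_ROOM) {
  if (any(resistance < 0)) abort("`resistance` must be non-negative.")
  if (any(temperature <= 0)) abort("`temperature` must be positive.")
  sqrt(4 * K_BOLTZMANN * temperature * resistance) * 1e9
}
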