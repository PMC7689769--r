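#' Cylindrical gradient-coil former
#'
#' @param radius former radius (m); must fit the 13.5-cm bore radius.
#' @param length former length (m). The reference geometry has a
#'   length-to-diameter ratio near 1:1.
#' @return a list of class `gradient_former`.
#' @export
gradient_former <- function(radius = 0.125, length = 0.35) {
  stopifnot(radius > 0, length > 0)
  if (radius >= 0.135) abort("former radius must be below the 0.135 m bore radius.")
  structure(list(radius = radius, length = length, axis = "x"),
            class = "gradient_former")
}

#' Ordered wire paths carrying a common current
#'
#' @param paths tibble with columns `path_id, x, y, z` (m); each path must
#'   be closed (first point repeated last) or marked as a lead via the
#'   optional logical column `lead`.
#' @param current common current (A).
#' @param wire_diameter wire diameter (m).
#' @return a list of class `wire_set`.
#' @export
wire_set <- function(paths, current = 1, wire_diameter = 0.0015) {
  stopifnot(is.data.frame(paths),
            all(c("path_id", "x", "y", "z") %in% names(paths)))
  for (id in unique(paths$path_id)) {
    p <- paths[paths$path_id == id, ]
    is_lead <- "lead" %in% names(p) && isTRUE(p$lead[1])
    closed <- nrow(p) >= 3 &&
      all(abs(unlist(p[1, c("x", "y", "z")]) -
                unlist(p[nrow(p), c("x", "y", "z")])) < 1e-12)
    if (!closed && !is_lead) {
      abort(sprintf("wire path %s is neither closed nor marked as a lead.", id))
    }
  }
  structure(list(paths = as_tibble(paths), current = current,
                 wire_diameter = wire_diameter),
            class = "wire_set")
}

# stream-function basis on the former surface, evaluated at (theta, x):
# [sin(m theta), cos(m theta)] x sin(n pi (x + L/2) / L), m = 1..m_max.
# The axial sines vanish at the former ends so every contour closes on the
# surface; the m = 0 (axisymmetric, solenoid-like) modes are omitted because
# they contribute no useful Bz for transverse-B0 encoding.
.stream_basis <- function(theta, x, L, m_max, n_ax) {
  cols <- vector("list", 2L * m_max * n_ax)
  k <- 0L
  for (m in seq_len(m_max)) {
    sm <- sin(m * theta); cm <- cos(m * theta)
    for (n in seq_len(n_ax)) {
      ax <- sin(n * pi * (x + L / 2) / L)
      cols[[k + 1L]] <- sm * ax
      cols[[k + 2L]] <- cm * ax
      k <- k + 2L
    }
  }
  do.call(cbind, cols)
}

#' Design a gradient coil by the target-field (stream-function) method
#'
#' Solves for a continuous surface current on the cylindrical former --
#' expressed through a stream function in an azimuthal x axial sine basis --
#' that reproduces `Bz = G * u` (u the requested axis coordinate; B0 is
#' along z, transverse to the bore) at the target points, with Tikhonov
#' regularization. The stream function is then discretized into closed wire
#' loops by contouring at equispaced levels, each loop carrying the level
#' spacing as its current. With the transverse main field the y and z coils
#' come out quadrupole-like, while the x (bore-axis) coil is a distinct
#' longitudinal pattern with field reversal beyond the former ends.
#'
#' The surface-current/dipole-sheet equivalence is used throughout: a
#' stream function `psi` on a surface produces the same field as a dipole
#' layer of moment density `psi * n_hat`, which reduces every design and
#' evaluation step to the point-dipole kernel.
#'
#' @param axis `"x"`, `"y"` or `"z"`: the coordinate the coil encodes.
#' @param former a [gradient_former()].
#' @param target_gradient requested gradient (mT/m).
#' @param target_region [dsv_region()] of target points; default a 15-cm DSV.
#' @param n_contours wire loops per current direction (levels are
#'   `2 * n_contours` across the full stream-function range).
#' @param lambda Tikhonov weight relative to the normal-matrix scale, or
#'   `"auto"` for an L-curve (maximum curvature) choice.
#' @param m_max,n_ax azimuthal and axial basis orders.
#' @param n_theta,n_x surface discretization for the design kernel.
#' @return a [wire_set()] with attributes `axis`, `stream` (solution
#'   internals) and `residual` (relative RMS target misfit of the
#'   continuous solution).
#' @export
design_gradient_coil <- function(axis = c("y", "z", "x"),
                                 former = gradient_former(),
                                 target_gradient = 1,
                                 target_region = dsv_region(0.15),
                                 n_contours = 12, lambda = 1e-4,
                                 m_max = 4, n_ax = 12,
                                 n_theta = 72, n_x = 70) {
  axis <- match.arg(axis)
  a <- former$radius
  L <- former$length
  if (target_region$diameter / 2 > a - 0.01) {
    abort("target region must fit inside the former with >= 1 cm margin.")
  }
  G <- target_gradient * 1e-3  # T/m
  theta <- 2 * pi * (seq_len(n_theta) - 0.5) / n_theta
  xg <- seq(-L / 2, L / 2, length.out = n_x + 1)
  xc <- (xg[-1] + xg[-(n_x + 1)]) / 2
  dA <- (2 * pi * a / n_theta) * (L / n_x)
  g <- expand.grid(theta = theta, x = xc)
  cen <- cbind(g$x, a * sin(g$theta), a * cos(g$theta))
  nrm <- cbind(0, sin(g$theta), cos(g$theta))
  Psi <- .stream_basis(g$theta, g$x, L, m_max, n_ax)
  tp <- .points_matrix(target_region$points)
  u <- tp[, match(axis, c("x", "y", "z"))]
  b <- G * u
  # Bz kernel of a unit-moment radial dipole at each patch
  P <- nrow(tp); np <- nrow(cen)
  dx <- outer(tp[, 1], cen[, 1], "-")
  dy <- outer(tp[, 2], cen[, 2], "-")
  dz <- outer(tp[, 3], cen[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  ir3 <- r2^(-1.5)
  nd <- sweep(dy, 2, nrm[, 2], "*") + sweep(dz, 2, nrm[, 3], "*")
  K <- 1e-7 * (3 * nd * dz * ir3 / r2 - matrix(nrm[, 3], P, np, byrow = TRUE) * ir3)
  A <- K %*% (Psi * dA)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  scl <- mean(diag(AtA))
  solve_for <- function(lam) solve(AtA + lam * scl * diag(ncol(A)), Atb)
  if (identical(lambda, "auto")) lambda <- .l_curve_lambda(A, b, AtA, Atb, scl)
  w <- solve_for(lambda)
  resid <- sqrt(mean((A %*% w - b)^2)) / (G * target_region$diameter / 2)
  if (resid > 0.05) {
    warn(sprintf(
      "continuous target misfit is %.1f%% RMS; the %s gradient may be unreachable on this former (consider a longer former or higher regularization).",
      resid * 100, axis))
  }
  stream <- list(w = as.vector(w), former = former, m_max = m_max, n_ax = n_ax,
                 lambda = lambda, patches = list(cen = cen, nrm = nrm, dA = dA,
                                                 theta = g$theta, x = g$x))
  cw <- .contour_stream(stream, n_contours)
  scale_current <- 1  # loops carry the level spacing; G0 matches the target
  paths <- purrr::map2_dfr(cw$paths, seq_along(cw$paths), function(m, i) {
    tibble(path_id = i, x = m[, 1], y = m[, 2], z = m[, 3])
  })
  ws <- wire_set(paths, current = cw$current * scale_current)
  attr(ws, "axis") <- axis
  attr(ws, "stream") <- stream
  attr(ws, "residual") <- resid
  attr(ws, "target_gradient") <- target_gradient
  ws
}

# L-curve corner by maximum curvature over a log-spaced lambda sweep
.l_curve_lambda <- function(A, b, AtA, Atb, scl) {
  lams <- 10^seq(-7, -1, length.out = 25)
  pts <- vapply(lams, function(lam) {
    w <- solve(AtA + lam * scl * diag(ncol(A)), Atb)
    c(log(sum((A %*% w - b)^2)) / 2, log(sum(w^2)) / 2)
  }, numeric(2))
  x <- pts[1, ]; y <- pts[2, ]
  d1x <- diff(x); d1y <- diff(y)
  d2x <- diff(d1x); d2y <- diff(d1y)
  curv <- abs(d1x[-1] * d2y - d1y[-1] * d2x) /
    (d1x[-1]^2 + d1y[-1]^2)^1.5
  lams[which.max(curv) + 1L]
}

# evaluate the stream function anywhere on the former
.stream_eval <- function(stream, theta, x) {
  g <- expand.grid(theta = theta, x = x)
  Psi <- .stream_basis(g$theta, g$x, stream$former$length, stream$m_max,
                       stream$n_ax)
  matrix(Psi %*% stream$w, length(theta), length(x))
}

# contour psi into closed loops. Contours are extracted on a tripled
# azimuthal domain so that every non-wrapping loop has at least one uncut
# copy, then deduplicated by (level, centroid mod 2 pi, area). Orientation:
# current keeps higher psi on its right in the (a*theta, x) chart, whose
# outward normal is -(u_hat x v_hat).
.contour_stream <- function(stream, n_contours, n_theta = 192, n_x = 151) {
  a <- stream$former$radius
  L <- stream$former$length
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  xn <- seq(-L / 2, L / 2, length.out = n_x)
  psi <- .stream_eval(stream, th, xn)
  th3 <- c(th, th + 2 * pi, th + 4 * pi)
  psi3 <- rbind(psi, psi, psi)
  rng <- max(abs(psi))
  levs <- seq(-rng, rng, length.out = 2 * n_contours + 1)
  levs <- (levs[-1] + levs[-length(levs)]) / 2
  dpsi <- levs[2] - levs[1]
  cl <- grDevices::contourLines(th3, xn, psi3, levels = levs)
  paths <- list(); seen <- character()
  for (cc in cl) {
    npt <- length(cc$x)
    if (!(cc$x[1] == cc$x[npt] && cc$y[1] == cc$y[npt])) next
    tt <- cc$x[-npt]; xx <- cc$y[-npt]
    ar <- abs(sum(tt * c(xx[-1], xx[1]) - c(tt[-1], tt[1]) * xx) / 2)
    key <- sprintf("%.6g|%.3f|%.4f|%.4g", cc$level, mean(tt) %% (2 * pi),
                   mean(xx), ar)
    if (key %in% seen) next
    seen <- c(seen, key)
    u <- a * cc$x; v <- cc$y
    el <- sqrt(diff(u)^2 + diff(v)^2)
    k <- which.max(el)
    tgt <- c(u[k + 1] - u[k], v[k + 1] - v[k]) / el[k]
    mid <- c((u[k] + u[k + 1]) / 2, (v[k] + v[k + 1]) / 2)
    delta <- min(2 * pi * a / n_theta, xn[2] - xn[1])
    pl <- .psi_bilinear(th, xn, psi, (mid[1] - delta * tgt[2]) / a,
                        mid[2] + delta * tgt[1])
    pr <- .psi_bilinear(th, xn, psi, (mid[1] + delta * tgt[2]) / a,
                        mid[2] - delta * tgt[1])
    xyz <- cbind(cc$y, a * sin(cc$x), a * cos(cc$x))
    if (pl > pr) xyz <- xyz[rev(seq_len(nrow(xyz))), ]
    paths[[length(paths) + 1L]] <- xyz
  }
  list(paths = paths, current = dpsi)
}

# bilinear interpolation, periodic in theta, clamped in x
.psi_bilinear <- function(th, xn, psi, tq, xq) {
  tq <- tq %% (2 * pi)
  nt <- length(th); dt <- th[2] - th[1]
  i <- floor((tq - th[1]) / dt); ft <- (tq - th[1]) / dt - i
  i1 <- (i %% nt) + 1; i2 <- (i + 1) %% nt + 1
  dxv <- xn[2] - xn[1]
  j <- pmin(pmax(floor((xq - xn[1]) / dxv), 0), length(xn) - 2)
  fx <- (xq - xn[1]) / dxv - j
  psi[i1, j + 1] * (1 - ft) * (1 - fx) + psi[i2, j + 1] * ft * (1 - fx) +
    psi[i1, j + 2] * (1 - ft) * fx + psi[i2, j + 2] * ft * fx
}

#' Efficiency and nonlinearity of a gradient coil
#'
#' Efficiency is the central gradient of Bz along the coil axis per ampere
#' (2-mm central finite difference, reported in mT/m/A). Nonlinearity is
#' `max |Bz - G0 u| / (G0 fov/2) * 100` over the evaluation points of a
#' cubic lattice restricted to the spherical field of view (the corners of
#' the full cube sit millimetres from the wires, where no cylindrical coil
#' is linear).
#'
#' @param wires a designed [wire_set()] (needs the `axis` attribute, or pass
#'   `axis`).
#' @param fov field-of-view diameter (m).
#' @param grid_spacing lattice spacing (m); 5 mm gives the 31^3 grid.
#' @param axis coil axis override.
#' @param current drive current (A).
#' @return list of class `gradient_performance`: `efficiency` (mT/m/A),
#'   `nonlinearity_max` (%), `field_map`, `resistance_estimate` (ohm),
#'   `fov`, `axis`.
#' @export
gradient_performance <- function(wires, fov = 0.15, grid_spacing = 0.005,
                                 axis = NULL, current = 1) {
  stopifnot(inherits(wires, "wire_set"))
  if (current <= 0) abort("`current` must be positive.")
  axis <- axis %||% attr(wires, "axis")
  if (is.null(axis)) abort("coil axis unknown; pass `axis`.")
  ic <- match(axis, c("x", "y", "z"))
  gseq <- seq(-fov / 2, fov / 2, by = grid_spacing)
  grid <- grid_points(gseq, gseq, gseq)
  keep <- with(grid, sqrt(x^2 + y^2 + z^2)) <= fov / 2 + 1e-12
  grid <- grid[keep, ]
  fm <- biot_savart(wires, grid, current = current)
  h <- 0.002
  pc <- matrix(0, 2, 3); pc[1, ic] <- -h; pc[2, ic] <- h
  bc <- biot_savart(wires, pc, current = current)$Bz
  G0 <- (bc[2] - bc[1]) / (2 * h)
  if (abs(G0) < 1e-15) abort("central gradient is zero; cannot normalize.")
  u <- .points_matrix(grid)[, ic]
  nl <- max(abs(fm$Bz - G0 * u)) / abs(G0 * fov / 2) * 100
  structure(
    list(efficiency = G0 / current * 1e3, nonlinearity_max = nl,
         field_map = fm, resistance_estimate = wire_resistance(wires),
         fov = fov, axis = axis),
    class = "gradient_performance"
  )
}

#' Rough DC resistance of a wire set
#'
#' Copper resistivity times total path length over the wire cross-section.
#'
#' @param wires a [wire_set()].
#' @param resistivity conductor resistivity (ohm m); copper by default.
#' @return resistance (ohm).
#' @export
wire_resistance <- function(wires, resistivity = 1.68e-8) {
  len <- 0
  for (id in unique(wires$paths$path_id)) {
    p <- as.matrix(wires$paths[wires$paths$path_id == id, c("x", "y", "z")])
    len <- len + sum(sqrt(rowSums(diff(p)^2)))
  }
  resistivity * len / (pi * (wires$wire_diameter / 2)^2)
}

#' Normalized encoding field map of a gradient coil
#'
#' Returns `Bz(r) / G0`, the spatially varying effective coordinate that
#' the coil actually encodes; it equals the true coordinate wherever the
#' coil is linear, and is the quantity consumed by the conjugate-phase
#' reconstruction.
#'
#' @param wires a designed [wire_set()].
#' @param points evaluation points (tibble or matrix, m).
#' @param axis coil axis override.
#' @return a tibble `x, y, z, coord` (effective coordinate, m).
#' @export
encoding_field_map <- function(wires, points, axis = NULL) {
  stopifnot(inherits(wires, "wire_set"))
  axis <- axis %||% attr(wires, "axis")
  if (is.null(axis)) abort("coil axis unknown; pass `axis`.")
  ic <- match(axis, c("x", "y", "z"))
  h <- 0.002
  pc <- matrix(0, 2, 3); pc[1, ic] <- -h; pc[2, ic] <- h
  bc <- biot_savart(wires, pc)$Bz
  G0 <- (bc[2] - bc[1]) / (2 * h)
  if (abs(G0) < 1e-15) abort("central gradient is zero; encoding map undefined.")
  fm <- biot_savart(wires, points)
  tibble(x = fm$x, y = fm$y, z = fm$z, coord = fm$Bz / G0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
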