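#' Describe a discretized Halbach magnet
#'
#' The magnet is a stack of `n_rings` rings along the bore (x) axis, each
#' ring holding two concentric layers of cube magnets in the k = 1
#' ("dipolar") Halbach orientation, which produces a homogeneous field
#' transverse to the bore (the z axis here). Ring radii refer to the inner
#' layer; the outer layer sits one magnet size plus `layer_gap` further out.
#'
#' @param n_rings number of rings (23 for the reference design).
#' @param bore_diameter clear bore (m).
#' @param length distance between the two outer rings (m).
#' @param magnet_size cube edge (m).
#' @param remanence magnet grade remanence Br (T); 1.42 T for N48.
#' @param magnets_per_layer cube magnets per layer. The default 64 matches
#'   the ~2950-magnet scale of the constructed 75-kg system.
#' @param ring_radii inner-layer radius per ring (m); a single value is
#'   recycled. Default: the uniform radius at which the design produces a
#'   mean field of `target_b0` over a 20-cm DSV (see
#'   [nominal_ring_radius()]).
#' @param layer_gap radial clearance between layers (m).
#' @param target_b0 design field level (T) used only when `ring_radii` is
#'   omitted.
#' @return a list of class `halbach_design` with a `rings` tibble
#'   (`ring, axial_position, r_inner, r_outer, n_inner, n_outer`).
#' @export
halbach_design <- function(n_rings = 23, bore_diameter = 0.27, length = 0.50,
                           magnet_size = 0.012, remanence = 1.42,
                           magnets_per_layer = 64, ring_radii = NULL,
                           layer_gap = 0.001, target_b0 = 0.05) {
  stopifnot(n_rings >= 1, length > 0, magnet_size > 0, magnets_per_layer >= 8)
  if (is.null(ring_radii)) {
    ring_radii <- nominal_ring_radius(
      target_b0 = target_b0, n_rings = n_rings, length = length,
      magnet_size = magnet_size, remanence = remanence,
      magnets_per_layer = magnets_per_layer, layer_gap = layer_gap,
      bore_diameter = bore_diameter
    )
  }
  ring_radii <- rep_len(ring_radii, n_rings)
  axial <- if (n_rings == 1) 0 else seq(-length / 2, length / 2, length.out = n_rings)
  rings <- tibble(
    ring = seq_len(n_rings),
    axial_position = axial,
    r_inner = ring_radii,
    r_outer = ring_radii + magnet_size + layer_gap,
    n_inner = as.integer(magnets_per_layer),
    n_outer = as.integer(magnets_per_layer)
  )
  design <- structure(
    list(rings = rings, bore_diameter = bore_diameter, length = length,
         magnet_size = magnet_size, remanence = remanence,
         layer_gap = layer_gap, b0_axis = "z"),
    class = "halbach_design"
  )
  .validate_halbach(design)
  design
}

.validate_halbach <- function(design) {
  r <- design$rings
  if (any(r$r_inner <= design$bore_diameter / 2)) {
    abort(sprintf("ring %d: inner radius must exceed the bore radius %.3f m.",
                  r$ring[which(r$r_inner <= design$bore_diameter / 2)[1]],
                  design$bore_diameter / 2))
  }
  for (i in seq_len(nrow(r))) {
    for (rad in c(r$r_inner[i], r$r_outer[i])) {
      arc <- 2 * pi * rad / r$n_inner[i]
      if (arc <= design$magnet_size) {
        abort(sprintf(
          "ring %d: magnets overlap azimuthally (arc spacing %.1f mm <= magnet size %.1f mm).",
          r$ring[i], arc * 1e3, design$magnet_size * 1e3))
      }
    }
  }
  invisible(design)
}

#' Uniform ring radius producing a given mean field
#'
#' Root-finds the single inner-layer radius at which a uniform-radius
#' Halbach design yields the requested mean field over a 20-cm DSV. Used to
#' center the ring-diameter search space on the intended operating field.
#'
#' @inheritParams halbach_design
#' @param dsv region over which the mean field is taken.
#' @param interval radius search interval (m).
#' @return radius (m).
#' @export
nominal_ring_radius <- function(target_b0 = 0.05, n_rings = 23, length = 0.50,
                                magnet_size = 0.012, remanence = 1.42,
                                magnets_per_layer = 64, layer_gap = 0.001,
                                bore_diameter = 0.27,
                                dsv = dsv_region(0.20),
                                interval = c(0.15, 0.30)) {
  pts <- .points_matrix(dsv$points)
  f <- function(r) {
    el <- .halbach_elements_matrix(
      radii = rep(r, n_rings),
      axial = if (n_rings == 1) 0 else seq(-length / 2, length / 2, length.out = n_rings),
      n_per_layer = magnets_per_layer, magnet_size = magnet_size,
      remanence = remanence, layer_gap = layer_gap
    )
    mean(.dipole_field_matrix(el$cen, el$mom, pts)[, 3]) - target_b0
  }
  uniroot(f, interval, tol = 1e-5)$root
}

# fast matrix-level element builder shared by the public API and the GA
.halbach_elements_matrix <- function(radii, axial, n_per_layer, magnet_size,
                                     remanence, layer_gap) {
  m0 <- remanence * magnet_size^3 / MU0
  phi <- 2 * pi * (seq_len(n_per_layer) - 1) / n_per_layer
  unit_pos <- cbind(sin(phi), cos(phi))      # (y, z) on the unit circle
  unit_mom <- cbind(sin(2 * phi), cos(2 * phi))
  nr <- length(radii)
  total <- nr * 2L * n_per_layer
  cen <- matrix(0, total, 3)
  mom <- matrix(0, total, 3)
  k <- 0L
  for (i in seq_len(nr)) {
    for (rad in c(radii[i], radii[i] + magnet_size + layer_gap)) {
      idx <- k + seq_len(n_per_layer)
      cen[idx, 1] <- axial[i]
      cen[idx, 2:3] <- rad * unit_pos
      mom[idx, 2:3] <- m0 * unit_mom
      k <- k + n_per_layer
    }
  }
  list(cen = cen, mom = mom)
}

#' Expand a Halbach design into magnet elements
#'
#' Magnets are evenly spaced in azimuth; a magnet at azimuth `phi` (measured
#' from the B0 (z) axis in the transverse plane) carries its moment at
#' `2 phi` -- the k = 1 Halbach rule that makes the ring field add up along
#' z inside the bore.
#'
#' @param design a [halbach_design()].
#' @return a [magnet_elements()] tibble.
#' @export
build_halbach_elements <- function(design) {
  stopifnot(inherits(design, "halbach_design"))
  .validate_halbach(design)
  r <- design$rings
  el <- .halbach_elements_matrix(r$r_inner, r$axial_position, r$n_inner[1],
                                 design$magnet_size, design$remanence,
                                 design$layer_gap)
  m0 <- design$remanence * design$magnet_size^3 / MU0
  magnet_elements(el$cen, el$mom / m0, remanence = design$remanence,
                  volume = design$magnet_size^3)
}

#' Optimize ring radii for field homogeneity
#'
#' Genetic-algorithm search over per-ring inner radii (mirror-symmetric
#' about the magnet midplane) minimizing the peak-to-peak homogeneity over a
#' DSV. Radii take values on a discrete grid, which lets per-ring field
#' contributions be precomputed once, so each fitness evaluation is a sum of
#' lookups.
#'
#' @param design template [halbach_design()]; its radii seed the population.
#' @param dsv [dsv_region()] objective region.
#' @param config [ga_config()].
#' @param radius_grid candidate inner radii (m). Default: nominal radius
#'   of the template's center ring +/- 2 cm in 1 mm steps.
#' @param mirror enforce mirror symmetry about the midplane (default TRUE).
#' @param target_b0 design field level (T). Homogenizing within free radius
#'   bounds systematically drifts the mean field, so the objective adds
#'   `field_weight * ((mean - target)/target)^2` to the ppm fitness, keeping
#'   the optimized magnet at its intended operating field. `NULL` optimizes
#'   homogeneity alone.
#' @param field_weight penalty scale (ppm-equivalent at 100% deviation).
#' @return a list of class `ring_optim`: `design` (optimized), `ppm`
#'   (homogeneity of the winner, penalty excluded), `mean_b0` (T), `trace`,
#'   `ga`.
#' @export
optimize_ring_diameters <- function(design, dsv = dsv_region(0.20),
                                    config = ga_config(),
                                    radius_grid = NULL, mirror = TRUE,
                                    target_b0 = 0.05, field_weight = 2e6) {
  stopifnot(inherits(design, "halbach_design"))
  r <- design$rings
  n <- nrow(r)
  if (is.null(radius_grid)) {
    mid <- r$r_inner[ceiling(n / 2)]
    radius_grid <- seq(mid - 0.02, mid + 0.02, by = 0.001)
  }
  if (any(radius_grid <= design$bore_diameter / 2)) {
    abort("radius grid infeasible: candidates inside the bore radius.")
  }
  arc <- 2 * pi * min(radius_grid) / r$n_inner[1]
  if (arc <= design$magnet_size) {
    abort("radius grid infeasible: magnets would overlap azimuthally.")
  }
  pts <- .points_matrix(dsv$points)
  nu <- if (mirror) ceiling(n / 2) else n
  nlev <- length(radius_grid)
  # precompute b0 (z) contribution of each (unique ring position, radius level)
  pre <- vector("list", nu)
  for (u in seq_len(nu)) {
    rings_u <- if (mirror && u < (n + 1) / 2) c(u, n + 1 - u) else u
    M <- matrix(0, nrow(pts), nlev)
    for (l in seq_len(nlev)) {
      el <- .halbach_elements_matrix(
        radii = rep(radius_grid[l], length(rings_u)),
        axial = r$axial_position[rings_u],
        n_per_layer = r$n_inner[1], magnet_size = design$magnet_size,
        remanence = design$remanence, layer_gap = design$layer_gap
      )
      M[, l] <- .dipole_field_matrix(el$cen, el$mom, pts)[, 3]
    }
    pre[[u]] <- M
  }
  fitness <- function(pop) {
    bz <- matrix(0, nrow(pts), nrow(pop))
    for (u in seq_len(nu)) bz <- bz + pre[[u]][, pop[, u], drop = FALSE]
    mu <- colMeans(bz)
    f <- (apply(bz, 2, max) - apply(bz, 2, min)) / mu * 1e6
    if (!is.null(target_b0)) {
      f <- f + field_weight * ((mu - target_b0) / target_b0)^2
    }
    f
  }
  # seed the population with the template design snapped to the grid
  init <- matrix(vapply(
    r$r_inner[seq_len(nu)],
    function(x) which.min(abs(radius_grid - x)), 1L
  ), nrow = 1)
  ga <- ga_optimize(fitness, rep(nlev, nu), config, init = init)
  best_r <- radius_grid[ga$best]
  radii <- if (mirror) c(best_r, rev(best_r[seq_len(n - nu)])) else best_r
  out <- design
  out$rings$r_inner <- radii
  out$rings$r_outer <- radii + design$magnet_size + design$layer_gap
  bz <- matrix(0, nrow(pts), 1)
  for (u in seq_len(nu)) bz <- bz + pre[[u]][, ga$best[u], drop = FALSE]
  structure(
    list(design = out, ppm = (max(bz) - min(bz)) / mean(bz) * 1e6,
         mean_b0 = mean(bz), trace = ga$trace, ga = ga),
    class = "ring_optim"
  )
}

#' Cylindrical ternary shim-magnet grid
#'
#' A cylindrical grid of candidate positions for small shim magnets: 15
#' rings of 60 positions on a 32.5-cm-diameter, 28-cm-long former. Each
#' position is ABSENT (0), ALIGNED with the local k = 1 Halbach orientation
#' (1), or FLIPPED 180 degrees from it (2).
#'
#' @param radius grid radius (m).
#' @param length grid length (m).
#' @param n_rings rings along the axis.
#' @param positions_per_ring azimuthal positions per ring; position 1 sits
#'   on the B0 (z) axis.
#' @param magnet_size shim cube edge (m); 3 mm.
#' @param remanence shim magnet remanence (T); 1.35 T for N45.
#' @param state integer matrix (`n_rings` x `positions_per_ring`) of
#'   {0, 1, 2}; defaults to all ABSENT.
#' @return a list of class `shim_grid`.
#' @export
shim_grid <- function(radius = 0.1625, length = 0.28, n_rings = 15,
                      positions_per_ring = 60, magnet_size = 0.003,
                      remanence = 1.35, state = NULL) {
  if (is.null(state)) state <- matrix(0L, n_rings, positions_per_ring)
  state <- matrix(as.integer(state), n_rings, positions_per_ring)
  if (!all(state %in% 0:2)) {
    abort("shim `state` entries must be 0 (absent), 1 (aligned) or 2 (flipped).")
  }
  structure(
    list(radius = radius, length = length, n_rings = as.integer(n_rings),
         positions_per_ring = as.integer(positions_per_ring),
         magnet_size = magnet_size, remanence = remanence, state = state),
    class = "shim_grid"
  )
}

# positions and aligned moments of every grid slot (matrix form)
.shim_slots <- function(grid) {
  xr <- if (grid$n_rings == 1) 0 else
    seq(-grid$length / 2, grid$length / 2, length.out = grid$n_rings)
  phi <- 2 * pi * (seq_len(grid$positions_per_ring) - 1) / grid$positions_per_ring
  g <- expand.grid(j = seq_len(grid$positions_per_ring), i = seq_len(grid$n_rings))
  cen <- cbind(xr[g$i], grid$radius * sin(phi[g$j]), grid$radius * cos(phi[g$j]))
  dir <- cbind(0, sin(2 * phi[g$j]), cos(2 * phi[g$j]))
  list(cen = cen, dir = dir, ring = g$i, pos = g$j)
}

#' Expand a shim grid into magnet elements
#'
#' ALIGNED positions follow the k = 1 Halbach orientation at their azimuth;
#' FLIPPED positions carry the opposite moment, whose field is the exact
#' negation of the aligned one.
#'
#' @param grid a [shim_grid()].
#' @return a [magnet_elements()] tibble (one row per non-absent position).
#' @export
build_shim_elements <- function(grid) {
  stopifnot(inherits(grid, "shim_grid"))
  slots <- .shim_slots(grid)
  s <- as.vector(t(grid$state))  # slot order: position fastest, ring outer
  keep <- s != 0L
  if (!any(keep)) {
    return(magnet_elements(matrix(0, 0, 3), matrix(0, 0, 3), 1, 1)[0, ])
  }
  sign <- ifelse(s[keep] == 1L, 1, -1)
  magnet_elements(slots$cen[keep, , drop = FALSE],
                  slots$dir[keep, , drop = FALSE] * sign,
                  remanence = grid$remanence, volume = grid$magnet_size^3)
}

#' Optimize the ternary shim grid against a measured or simulated field
#'
#' Minimizes the peak-to-peak homogeneity of `base field + shim field` over
#' the DSV with the integer GA (ternary genes). The all-ABSENT state is
#' seeded into the initial population, so the result never does worse than
#' no shimming.
#'
#' @param base_field a `field_map` evaluated at the DSV sample points (the
#'   points of `dsv$points` must all be present in `base_field`, within
#'   1e-6 m); use [dipole_field()] or [read_field_map_csv()] to produce it.
#' @param grid a [shim_grid()] defining the candidate positions.
#' @param dsv [dsv_region()].
#' @param config [ga_config()].
#' @return a list of class `shim_optim`: `grid` (optimized state), `ppm`,
#'   `ppm_unshimmed`, `trace`, `ga`.
#' @export
optimize_shim <- function(base_field, grid, dsv = dsv_region(0.20),
                          config = ga_config()) {
  stopifnot(inherits(grid, "shim_grid"))
  pts <- .points_matrix(dsv$points)
  base <- .match_field_points(base_field, pts)
  slots <- .shim_slots(grid)
  m0 <- grid$remanence * grid$magnet_size^3 / MU0
  # per-slot aligned b0(z) contribution; flipped is its negation
  M <- matrix(0, nrow(pts), nrow(slots$cen))
  chunk <- 200L
  for (s0 in seq(1, nrow(slots$cen), by = chunk)) {
    idx <- seq(s0, min(s0 + chunk - 1L, nrow(slots$cen)))
    for (k in idx) {
      M[, k] <- .dipole_field_matrix(slots$cen[k, , drop = FALSE],
                                     slots$dir[k, , drop = FALSE] * m0,
                                     pts)[, 3]
    }
  }
  sgn_lut <- c(0, 1, -1)
  fitness <- function(pop) {
    S <- matrix(sgn_lut[pop + 1L], nrow(pop), ncol(pop))
    bz <- base + M %*% t(S)
    mu <- colMeans(bz)
    (apply(bz, 2, max) - apply(bz, 2, min)) / mu * 1e6
  }
  ngenes <- grid$n_rings * grid$positions_per_ring
  init <- matrix(1L, 1, ngenes)  # gene value 1 == state 0 (absent)
  ga <- ga_optimize(function(pop) fitness(pop - 1L), rep(3L, ngenes),
                    config, init = init)
  state <- matrix(ga$best - 1L, grid$n_rings, grid$positions_per_ring,
                  byrow = TRUE)
  out <- grid
  out$state <- state
  ppm0 <- (max(base) - min(base)) / mean(base) * 1e6
  structure(
    list(grid = out, ppm = ga$best_fitness, ppm_unshimmed = ppm0,
         trace = ga$trace, ga = ga),
    class = "shim_optim"
  )
}

# extract base-field b0 at the requested points (order-preserving)
.match_field_points <- function(field, pts) {
  fp <- cbind(field$x, field$y, field$z)
  idx <- integer(nrow(pts))
  # hash on rounded coordinates for exact-grid matches
  key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9), round(m[, 3], 9))
  lut <- setNames(seq_len(nrow(fp)), key(fp))
  idx <- lut[key(pts)]
  if (anyNA(idx)) {
    abort(paste0(
      "the DSV sample points are not covered by `base_field`; evaluate the ",
      "field on `dsv$points` (or resample the measured map onto them) first."
    ))
  }
  field$b0[idx]
}
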