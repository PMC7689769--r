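test_that("a single Halbach ring produces a clean transverse central field", {
  d <- halbach_design(n_rings = 1, length = 0.1, magnets_per_layer = 16,
                      ring_radii = 0.16)
  el <- build_halbach_elements(d)
  expect_equal(nrow(el), 32)  # 16 magnets x 2 layers
  ctr <- dipole_field(el, grid_points(0, 0, 0))
  expect_gt(ctr$Bz, 0)
  expect_lt(abs(ctr$Bx) / ctr$Bz, 1e-4)
  expect_lt(abs(ctr$By) / ctr$Bz, 1e-4)

  # flipping every moment reverses the central field exactly
  flipped <- el
  flipped[c("mx", "my", "mz")] <- -el[c("mx", "my", "mz")]
  expect_equal(dipole_field(flipped, grid_points(0, 0, 0))$Bz, -ctr$Bz,
               tolerance = 1e-12)

  # placing the magnets at azimuths shifted by the inter-magnet angle (the
  # k = 1 moment rule following the new azimuths) leaves the center unchanged
  ang <- 2 * pi / 16
  phi <- 2 * pi * (seq_len(16) - 1) / 16 + ang / 2
  el_r <- NULL
  for (rad in c(0.16, 0.16 + 0.012 + 0.001)) {
    el_r <- dplyr::bind_rows(el_r, magnet_elements(
      cbind(0, rad * sin(phi), rad * cos(phi)),
      cbind(0, sin(2 * phi), cos(2 * phi)),
      remanence = 1.42, volume = 0.012^3))
  }
  ctr_r <- dipole_field(el_r, grid_points(0, 0, 0))
  expect_equal(ctr_r$Bz, ctr$Bz, tolerance = 1e-6)
})

test_that("overlapping magnets on a ring are rejected with the ring index", {
  expect_error(
    halbach_design(n_rings = 2, magnets_per_layer = 80, ring_radii = 0.14),
    "ring 1.*overlap"
  )
})

test_that("mirror-symmetric designs give midplane-symmetric fields", {
  d <- halbach_design(n_rings = 5, length = 0.3, magnets_per_layer = 24,
                      ring_radii = c(0.18, 0.17, 0.165, 0.17, 0.18))
  el <- build_halbach_elements(d)
  pts_p <- grid_points(0.08, c(0, 0.03), c(0.02, -0.04))
  pts_m <- pts_p
  pts_m$x <- -pts_m$x
  bp <- dipole_field(el, pts_p)
  bm <- dipole_field(el, pts_m)
  expect_equal(bp$Bz, bm$Bz, tolerance = 1e-9)
})

test_that("ring-diameter GA finds the exhaustive optimum on a toy problem", {
  d <- halbach_design(n_rings = 3, length = 0.2, magnets_per_layer = 24,
                      ring_radii = 0.17)
  grid5 <- seq(0.16, 0.20, by = 0.01)
  dsv <- dsv_region(0.12)
  opt <- optimize_ring_diameters(d, dsv, toy_ga(seed = 3, pop = 40, gen = 40),
                                 radius_grid = grid5, target_b0 = NULL)
  # exhaustive oracle over the mirrored search space (5 x 5 combos)
  pts <- dsv$points
  best <- Inf
  for (r1 in grid5) for (r2 in grid5) {
    di <- halbach_design(n_rings = 3, length = 0.2, magnets_per_layer = 24,
                         ring_radii = c(r1, r2, r1))
    fm <- dipole_field(build_halbach_elements(di), pts)
    best <- min(best, homogeneity_ppm(fm))
  }
  expect_equal(opt$ppm, best, tolerance = 1e-9)
})

test_that("seeding the GA with the optimum keeps fitness monotone and flat", {
  d <- halbach_design(n_rings = 3, length = 0.2, magnets_per_layer = 24,
                      ring_radii = 0.17)
  grid5 <- seq(0.16, 0.20, by = 0.01)
  dsv <- dsv_region(0.12)
  o1 <- optimize_ring_diameters(d, dsv, toy_ga(seed = 3, pop = 40, gen = 40),
                                radius_grid = grid5, target_b0 = NULL)
  seeded <- d
  seeded$rings$r_inner <- o1$design$rings$r_inner
  o2 <- optimize_ring_diameters(seeded, dsv,
                                toy_ga(seed = 5, pop = 20, gen = 10),
                                radius_grid = grid5, target_b0 = NULL)
  expect_lte(o2$ppm, o1$ppm + 1e-9)
  expect_true(all(diff(o2$trace$best) <= 1e-12))
})

test_that("shim grid expansion respects state semantics", {
  g0 <- shim_grid()
  expect_equal(nrow(build_shim_elements(g0)), 0)     # all absent
  g1 <- shim_grid(state = matrix(1L, 15, 60))
  el <- build_shim_elements(g1)
  expect_equal(nrow(el), 900)                        # all aligned
  expect_error(shim_grid(state = matrix(3L, 15, 60)), "0.*1.*2")

  # a flipped magnet's field is the exact negation of its aligned field
  st_a <- matrix(0L, 15, 60); st_a[4, 17] <- 1L
  st_f <- matrix(0L, 15, 60); st_f[4, 17] <- 2L
  pts <- grid_points(c(0, 0.05), c(0.02, -0.06), c(0, 0.04))
  fa <- dipole_field(build_shim_elements(shim_grid(state = st_a)), pts)
  ff <- dipole_field(build_shim_elements(shim_grid(state = st_f)), pts)
  expect_equal(ff$Bz, -fa$Bz, tolerance = 1e-15)
  expect_equal(ff$Bx, -fa$Bx, tolerance = 1e-15)
})

test_that("shim superposition: state field equals sum of member fields", {
  set.seed(7)
  dsvp <- dsv_points(0.2, n_shells = 2, n_per_shell = 10)
  for (rep in 1:3) {
    st <- matrix(0L, 15, 60)
    on <- sample(900, 12)
    st[on] <- sample(1:2, 12, replace = TRUE)
    g <- shim_grid(state = st)
    total <- dipole_field(build_shim_elements(g), dsvp)$b0
    acc <- 0
    for (k in on) {
      st1 <- matrix(0L, 15, 60); st1[k] <- st[k]
      acc <- acc + dipole_field(build_shim_elements(shim_grid(state = st1)),
                                dsvp)$b0
    }
    expect_equal(total, acc, tolerance = 1e-12)
  }
})

test_that("shim GA matches exhaustive search on a 6-position grid", {
  # tiny grid: 2 rings x 3 positions = 6 ternary genes, 729 states
  grid <- shim_grid(radius = 0.12, length = 0.1, n_rings = 2,
                    positions_per_ring = 3)
  dsv <- dsv_region(0.1)
  # synthetic imperfect base field: uniform 50 mT plus a gradient across z
  pts <- dsv$points
  b0 <- 0.05 + 2e-4 * pts$z / 0.05 + 1e-4 * pts$y / 0.05
  base <- tibble::tibble(x = pts$x, y = pts$y, z = pts$z,
                         Bx = 0, By = 0, Bz = b0, b0 = b0)
  opt <- optimize_shim(base, grid, dsv, toy_ga(seed = 2, pop = 50, gen = 60))
  # exhaustive oracle over all 3^6 states
  slots <- expand.grid(rep(list(0:2), 6))
  best <- Inf
  for (r in seq_len(nrow(slots))) {
    st <- matrix(as.integer(slots[r, ]), 2, 3, byrow = TRUE)
    el <- build_shim_elements(shim_grid(radius = 0.12, length = 0.1,
                                        n_rings = 2, positions_per_ring = 3,
                                        state = st))
    shim_b0 <- if (nrow(el)) dipole_field(el, pts)$b0 else 0
    tot <- b0 + shim_b0
    best <- min(best, (max(tot) - min(tot)) / mean(tot) * 1e6)
  }
  expect_equal(opt$ppm, best, tolerance = 1e-9)
})

test_that("shim GA never does worse than the unshimmed state", {
  grid <- shim_grid(n_rings = 4, positions_per_ring = 12)
  dsv <- dsv_region(0.15)
  pts <- dsv$points
  b0 <- rep(0.05, nrow(pts))
  base <- tibble::tibble(x = pts$x, y = pts$y, z = pts$z,
                         Bx = 0, By = 0, Bz = b0, b0 = b0)
  opt <- optimize_shim(base, grid, dsv, toy_ga(seed = 1, pop = 20, gen = 10))
  expect_lte(opt$ppm, opt$ppm_unshimmed + 1e-9)
})

test_that("optimizer trajectories are bit-identical for identical seeds", {
  d <- halbach_design(n_rings = 3, length = 0.2, magnets_per_layer = 24,
                      ring_radii = 0.17)
  cfg <- toy_ga(seed = 11, pop = 20, gen = 15)
  o1 <- optimize_ring_diameters(d, dsv_region(0.12), cfg,
                                radius_grid = seq(0.16, 0.20, 0.01),
                                target_b0 = NULL)
  o2 <- optimize_ring_diameters(d, dsv_region(0.12), cfg,
                                radius_grid = seq(0.16, 0.20, 0.01),
                                target_b0 = NULL)
  expect_identical(o1$ga$best, o2$ga$best)
  expect_identical(o1$trace, o2$trace)
  expect_identical(o1$design$rings$r_inner, o2$design$rings$r_inner)
})
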