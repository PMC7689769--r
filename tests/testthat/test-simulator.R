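test_that("tube-grid phantom has 45 tubes of the right volume", {
  ph <- tube_grid_phantom(voxel_mm = 1)
  # 45 distinct connected components, counted on the central slice stack
  img <- image_volume(ph$rho, ph$spacing)
  met <- distortion_metrics(img, tube_grid_centers(), threshold = 0.5)
  expect_equal(met$n_detected, 45)
  expect_equal(met$rms_mm, 0, tolerance = 1e-9)
  # analytic cylinder volume: 45 * pi r^2 h within 2% at 1-mm voxels
  vol <- sum(ph$rho) * prod(ph$spacing)
  expect_equal(vol, 45 * pi * 4^2 * 35, tolerance = 0.02)
  expect_error(tube_grid_phantom(grid_pitch_mm = 0), "overlap")
  expect_error(tube_grid_phantom(voxel_mm = 4.1), "voxel")
})

test_that("tissue phantoms carry the published relaxation values", {
  br <- tissue_phantom("brain", n = 24, voxel_mm = 8)
  expect_true(any(br$t1 == 1750))                    # CSF compartments
  expect_equal(unique(br$t2[br$t1 == 1750]), 0.9 * 1750)
  expect_true(any(br$t1 == 500 & br$t2 == 250))      # brain tissue

  kn <- tissue_phantom("knee", n = 24, voxel_mm = 6)
  lab <- unique(cbind(kn$t1[kn$rho > 0], kn$t2[kn$rho > 0]))
  lab <- lab[order(lab[, 1]), ]
  expect_equal(lab, rbind(c(70, 20), c(140, 84), c(200, 47)))

  solid <- tissue_phantom("brain", n = 16, voxel_mm = 10, ventricle_scale = 0)
  expect_equal(sort(unique(solid$t1[solid$rho > 0])), 500)
})

test_that("contrast weighting follows the saturation/inversion closed forms", {
  p <- tse_params(matrix = c(16, 8, 8), tr = 1e9, te = 10, etl = 1)
  expect_equal(contrast_weighting(500, 250, p, effective_te = 0), 1,
               tolerance = 1e-6)
  # inversion nulling at TI = T1 ln 2 with long TR
  pn <- tse_params(matrix = c(16, 8, 8), tr = 1e7, te = 10, etl = 1,
                   ti = 500 * log(2))
  expect_equal(
    contrast_weighting(500, 250, pn, "inversion_recovery", effective_te = 0),
    0, tolerance = 1e-3)
  # CSF is dark in the rapid T1-weighted protocol: recovery factor 0.249
  expect_equal(1 - exp(-500 / 1750), 0.2485, tolerance = 1e-3)
  pt1 <- tse_params(matrix = c(16, 8, 8), tr = 500, te = 10, etl = 1)
  w <- contrast_weighting(1750, 0.9 * 1750, pt1, effective_te = 0)
  expect_equal(w, 1 - exp(-500 / 1750), tolerance = 1e-12)
})

test_that("forward simulation reduces to the DFT and matches brute force", {
  set.seed(5)
  n <- 12
  rho <- array(0, c(n, n, n))
  rho[4:9, 3:10, 5:8] <- array(runif(6 * 8 * 4), c(6, 8, 4))
  ph <- mri_phantom(rho, array(800, dim(rho)), array(100, dim(rho)),
                    spacing = 10)
  p <- tse_params(fov = rep(n * 10, 3), matrix = c(n, n, n), tr = 1000,
                  te = 10, etl = 4, elliptical = FALSE)
  sched <- echo_train_schedule(p)
  ks <- simulate_acquisition(ph, identity_encoding_maps(ph), sched)

  # DC sample equals the total proton density
  c0 <- floor(n / 2) + 1
  expect_equal(ks$samples[c0, c0, c0], sum(rho) + 0i, tolerance = 1e-10)

  # brute-force centered-DFT oracle on a subset of k-space points
  kidx <- expand.grid(jx = c(-n / 2, 0, 2), j1 = c(-2, 1), j2 = c(0, 3))
  oracle <- brute_force_kspace(rho, ph$spacing, p$fov, kidx)
  got <- mapply(function(jx, j1, j2) {
    ks$samples[jx + c0, j1 + c0, j2 + c0]
  }, kidx$jx, kidx$j1, kidx$j2)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("symmetric real phantoms give Hermitian k-space", {
  n <- 8
  rho <- array(0, c(n, n, n))
  cc <- (seq_len(n) - 1 - n / 2)
  r2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  rho[r2 <= 9] <- 1                      # centered symmetric ball
  ph <- mri_phantom(rho, array(500, dim(rho)), array(100, dim(rho)), 8)
  p <- tse_params(fov = rep(64, 3), matrix = c(n, n, n), tr = 500, te = 10,
                  etl = 2, elliptical = FALSE)
  ks <- simulate_acquisition(ph, identity_encoding_maps(ph),
                             echo_train_schedule(p))
  c0 <- n / 2 + 1
  for (tr in 1:20) {
    i <- sample(2:n, 3, replace = TRUE)
    a <- ks$samples[i[1], i[2], i[3]]
    b <- ks$samples[2 * c0 - i[1], 2 * c0 - i[2], 2 * c0 - i[3]]
    expect_equal(a, Conj(b), tolerance = 1e-9)
  }
  # windowing with the real separable filter preserves Hermitian symmetry
  kw <- window_filter(ks)
  a <- kw$samples[3, 5, 2]
  b <- kw$samples[2 * c0 - 3, 2 * c0 - 5, 2 * c0 - 2]
  expect_equal(a, Conj(b), tolerance = 1e-9)
})

test_that("simulation is linear in the phantom", {
  n <- 8
  mk <- function(seed) {
    set.seed(seed)
    rho <- array(runif(n^3) * (runif(n^3) > 0.6), c(n, n, n))
    mri_phantom(rho + 1e-9, array(500, c(n, n, n)), array(100, c(n, n, n)), 8)
  }
  p <- tse_params(fov = rep(64, 3), matrix = c(n, n, n), tr = 500, te = 10,
                  etl = 2, elliptical = FALSE)
  sched <- echo_train_schedule(p)
  ph1 <- mk(1); ph2 <- mk(2)
  ph12 <- mri_phantom(ph1$rho + ph2$rho, ph1$t1, ph1$t2, 8)
  k1 <- simulate_acquisition(ph1, identity_encoding_maps(ph1), sched)
  k2 <- simulate_acquisition(ph2, identity_encoding_maps(ph2), sched)
  k12 <- simulate_acquisition(ph12, identity_encoding_maps(ph12), sched)
  expect_equal(k12$samples, k1$samples + k2$samples, tolerance = 1e-9)
})

test_that("complex noise has the configured variance and is seeded", {
  n <- 72
  rho <- array(1, c(n, n, 1))
  ph <- mri_phantom(rho, array(500, dim(rho)), array(100, dim(rho)), 8)
  p <- tse_params(fov = c(128, 128, 128), matrix = c(n, n, 1), tr = 500,
                  te = 10, etl = 2, elliptical = FALSE)
  sched <- echo_train_schedule(p)
  maps <- identity_encoding_maps(ph)
  clean <- simulate_acquisition(ph, maps, sched)
  sd0 <- 0.37
  noisy <- simulate_acquisition(ph, maps, sched,
                                acq_config(noise_sd = sd0, seed = 9))
  resid <- noisy$samples - clean$samples
  draws <- c(Re(resid), Im(resid))
  expect_equal(stats::var(draws), sd0^2, tolerance = 0.05)
  # same seed, same noise; different seed, different noise
  noisy2 <- simulate_acquisition(ph, maps, sched,
                                 acq_config(noise_sd = sd0, seed = 9))
  expect_identical(noisy$samples, noisy2$samples)
  noisy3 <- simulate_acquisition(ph, maps, sched,
                                 acq_config(noise_sd = sd0, seed = 10))
  expect_false(identical(noisy$samples, noisy3$samples))
})

test_that("mismatched encoding maps are rejected", {
  ph <- mri_phantom(array(1, c(4, 4, 4)), array(500, c(4, 4, 4)),
                    array(100, c(4, 4, 4)), 10)
  maps <- encoding_maps(array(0, c(5, 5, 5)), array(0, c(5, 5, 5)),
                        array(0, c(5, 5, 5)))
  p <- tse_params(matrix = c(4, 4, 4), tr = 500, te = 10, etl = 1,
                  elliptical = FALSE)
  expect_error(
    simulate_acquisition(ph, maps, echo_train_schedule(p)),
    "do not match")
})
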