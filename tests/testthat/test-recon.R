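# small helper: simulate a phantom with identity maps on its own grid
sim_identity <- function(rho, spacing = 8, etl = 2, fov = NULL) {
  d <- dim(rho)
  ph <- mri_phantom(rho + 0, array(500, d), array(100, d), spacing)
  p <- tse_params(fov = fov %||% (d * rep_len(spacing, 3)), matrix = d,
                  tr = 500, te = 10, etl = etl, elliptical = FALSE)
  list(ph = ph,
       ks = simulate_acquisition(ph, identity_encoding_maps(ph),
                                 echo_train_schedule(p)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("window peaks at the k-space center and records the DC scale", {
  rho <- array(1, c(8, 8, 8))
  ks <- sim_identity(rho)$ks
  kw <- window_filter(ks)
  w1 <- abs(kw$samples[, 5, 5]) / pmax(abs(ks$samples[, 5, 5]), 1e-300)
  expect_equal(which.max(w1), 5)
  expect_equal(max(w1), attr(kw, "dc_scale")^(1 / 3), tolerance = 1e-6)
  expect_identical(window_filter(ks, "none"), ks)
})

test_that("windowing broadens the PSF by the analytic window transform", {
  # point source at the center -> flat k-space; windowed PSF equals the
  # window's own transform, whose FWHM we compute independently
  n <- 64
  rho <- array(0, c(n, n, 1)); rho[n / 2 + 1, n / 2 + 1, 1] <- 1
  ks <- sim_identity(rho, spacing = 4)$ks
  img0 <- ifft_recon(ks)
  img1 <- ifft_recon(window_filter(ks))
  prof0 <- img0$voxels[, n / 2 + 1, 1]
  prof1 <- img1$voxels[, n / 2 + 1, 1]
  # oracle: highly zero-padded |FFT| of the analytic window
  w <- sin(pi * (seq_len(n) - 1) / n)^2
  pad <- 64
  wz <- rep(0, n * pad); wz[seq_len(n)] <- w
  psf <- abs(fft(wz))
  psf <- c(psf[(length(psf) / 2 + 1):length(psf)], psf[seq_len(length(psf) / 2)])
  fw_expected <- halbachmri:::.fwhm(psf) / pad
  # measure the windowed image PSF by fine interpolation
  up <- approx(seq_len(n), prof1, xout = seq(1, n, by = 1 / 64))
  fw_measured <- halbachmri:::.fwhm(up$y) / 64
  expect_equal(fw_measured, fw_expected, tolerance = 0.05)
  expect_gt(fw_measured, halbachmri:::.fwhm(approx(seq_len(n), prof0,
    xout = seq(1, n, by = 1 / 64))$y) / 64)
})

test_that("inverse FFT obeys the point-source and Parseval identities", {
  d <- c(8, 8, 8)
  p <- tse_params(fov = c(64, 64, 64), matrix = d, tr = 500, te = 10,
                  etl = 1, elliptical = FALSE)
  sched <- echo_train_schedule(p)
  samples <- array(0i, d); samples[5, 5, 5] <- 1
  ks <- structure(list(samples = samples, mask = array(TRUE, d[2:3]),
                       schedule = sched, dwell_s = 1 / p$bandwidth,
                       params = p), class = "kspace_data")
  img <- ifft_recon(ks)
  expect_equal(max(img$voxels) / min(img$voxels), 1, tolerance = 1e-12)
  # Parseval: sum |image|^2 = sum |k|^2 / N
  set.seed(3)
  samples2 <- array(complex(real = rnorm(prod(d)),
                            imaginary = rnorm(prod(d))), d)
  ks$samples <- samples2
  img2 <- ifft_recon(ks)
  expect_equal(sum(img2$voxels^2), sum(Mod(samples2)^2) / prod(d),
               tolerance = 1e-10)
})

test_that("simulate -> ifft round-trips the phantom under identity maps", {
  set.seed(11)
  rho <- array(runif(12^3) * (runif(12^3) > 0.5), c(12, 12, 12))
  out <- sim_identity(rho)
  img <- ifft_recon(out$ks)
  expect_lt(max(abs(img$voxels - rho)) / max(rho), 1e-8)
})

test_that("conjugate-phase recon equals the inverse FFT under identity maps", {
  for (n in c(8, 16)) {
    set.seed(n)
    rho <- array(runif(n^3) * (runif(n^3) > 0.4), c(n, n, n))
    out <- sim_identity(rho)
    maps <- identity_encoding_maps(out$ph)
    a <- ifft_recon(out$ks)$voxels
    b <- conjugate_phase_recon(out$ks, maps)$voxels
    expect_lt(max(abs(a - b)) / max(a), 1e-10)
  }
})

test_that("conjugate-phase recon restores a point distorted by a nonlinear map", {
  n <- 32
  rho <- array(0, c(n, n, 1))
  ix <- n / 2 + 1 + 8                      # off-center point at +8 voxels
  rho[ix, n / 2 + 1, 1] <- 1
  ph <- mri_phantom(rho, array(500, dim(rho)), array(100, dim(rho)),
                    spacing = 4)
  p <- tse_params(fov = c(128, 128, 128), matrix = c(n, n, 1), tr = 500,
                  te = 10, etl = 2, elliptical = FALSE)
  sched <- echo_train_schedule(p)
  maps <- identity_encoding_maps(ph)
  # compressive nonlinearity along x: g(x) = x (1 - a x^2 / L^2)
  Lm <- 0.064
  nonlin <- function(x) x * (1 - 0.8 * (x / Lm)^2)
  maps$gx <- nonlin(maps$gx)
  ks <- simulate_acquisition(ph, maps, sched)
  img_u <- ifft_recon(ks)
  img_c <- conjugate_phase_recon(ks, maps)
  true_x <- (ix - 1 - n / 2) * 4
  peak_u <- (which.max(img_u$voxels[, n / 2 + 1, 1]) - 1 - n / 2) * 4
  peak_c <- (which.max(img_c$voxels[, n / 2 + 1, 1]) - 1 - n / 2) * 4
  # uncorrected image puts the point at its encoded (distorted) position
  enc_x <- nonlin(true_x / 1000) * 1000
  expect_lt(abs(peak_u - enc_x), 4)        # within a voxel of the distortion
  expect_gt(abs(peak_u - true_x), 4)       # clearly displaced
  expect_lt(abs(peak_c - true_x), 4 + 1e-9)  # restored within one voxel
})

test_that("conjugate-phase recon is linear in the k-space data", {
  n <- 8
  set.seed(2)
  out <- sim_identity(array(runif(n^3), c(n, n, n)))
  maps <- identity_encoding_maps(out$ph)
  k1 <- out$ks
  k2 <- out$ks
  set.seed(4)
  k2$samples <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)),
                      dim(k1$samples))
  ksum <- k1; ksum$samples <- k1$samples + k2$samples
  a <- conjugate_phase_recon(k1, maps, magnitude = FALSE)$voxels
  b <- conjugate_phase_recon(k2, maps, magnitude = FALSE)$voxels
  s <- conjugate_phase_recon(ksum, maps, magnitude = FALSE)$voxels
  expect_equal(s, a + b, tolerance = 1e-10)
})

test_that("drift correction restores the drift-free acquisition", {
  n <- 32
  rho <- array(0, c(n, n, 1)); rho[n / 2 + 1 + 5, n / 2 + 1, 1] <- 1
  ph <- mri_phantom(rho, array(500, dim(rho)), array(100, dim(rho)), 4)
  # long scan so 800 Hz/h drift accumulates to ~160 Hz by the end
  p <- tse_params(fov = c(128, 128, 128), matrix = c(n, n, 1), tr = 22500,
                  te = 10, etl = 1, elliptical = FALSE)
  sched <- echo_train_schedule(p)
  maps <- identity_encoding_maps(ph)
  dm <- drift_model(800)
  ks0 <- simulate_acquisition(ph, maps, sched)
  ksd <- simulate_acquisition(ph, maps, sched, acq_config(drift = dm))
  expect_gt(max(abs(ksd$samples - ks0$samples)), 1e-3)  # drift did something
  ksc <- drift_phase_correction(ksd, dm)
  expect_equal(ksc$samples, ks0$samples, tolerance = 1e-12)
  # zero drift is the identity
  ks_id <- drift_phase_correction(ks0, drift_model(0))
  expect_identical(ks_id$samples, ks0$samples)
  # PSF after correction matches the drift-free PSF to < 0.1 pixel
  prof <- function(k) {
    v <- ifft_recon(k)$voxels[, n / 2 + 1, 1]
    up <- approx(seq_len(n), v, xout = seq(1, n, by = 1 / 64))$y
    halbachmri:::.fwhm(up) / 64
  }
  expect_lt(abs(prof(ksc) - prof(ks0)), 0.1)
})

test_that("distortion metrics recover exact and shifted grids", {
  # perfect synthetic 3 x 3 grid of gaussian blobs
  n <- 48
  spacing <- 2
  cc <- (seq_len(n) - 1 - n / 2) * spacing
  refs <- expand.grid(x = c(-24, 0, 24), y = c(-24, 0, 24))
  mkimg <- function(dx) {
    v <- array(0, c(n, n, 1))
    for (r in seq_len(nrow(refs))) {
      g <- outer(exp(-(cc - refs$x[r] - dx)^2 / 18),
                 exp(-(cc - refs$y[r])^2 / 18))
      v[, , 1] <- v[, , 1] + g
    }
    image_volume(v, spacing)
  }
  m0 <- distortion_metrics(mkimg(0), cbind(refs$x, refs$y, 0))
  expect_equal(m0$n_detected, 9)
  expect_equal(m0$rms_mm, 0, tolerance = 1e-6)
  # grid shifted by exactly two voxels
  m2 <- distortion_metrics(mkimg(2 * spacing), cbind(refs$x, refs$y, 0))
  expect_equal(m2$rms_mm, 2 * spacing, tolerance = 1e-6)
  # greedy matching agrees with the exhaustive assignment oracle
  set.seed(8)
  jit <- mkimg(0)
  m1 <- distortion_metrics(mkimg(1.5), cbind(refs$x, refs$y, 0))
  blobs <- as.matrix(m1$per_blob[, c("x", "y", "z")])
  oracle <- brute_force_assignment_rms(blobs, as.matrix(cbind(refs, 0)))
  expect_equal(m1$rms_mm, oracle, tolerance = 1e-9)
})
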