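#' Digital phantom container
#'
#' Voxel grids of proton density and relaxation times on a centered
#' Cartesian lattice: voxel `i` (1-based, per dimension) sits at
#' `(i - 1 - floor(N/2)) * spacing` mm.
#'
#' @param rho proton density 3-D array (arbitrary units, >= 0).
#' @param t1,t2 relaxation times (ms), arrays congruent with `rho`.
#' @param spacing voxel size (mm), length 1 or 3.
#' @return a list of class `mri_phantom`.
#' @export
mri_phantom <- function(rho, t1, t2, spacing) {
  stopifnot(length(dim(rho)) == 3, all(dim(rho) == dim(t1)),
            all(dim(rho) == dim(t2)))
  if (any(rho < 0)) abort("`rho` must be non-negative.")
  sel <- rho > 0
  if (any(t1[sel] <= 0) || any(t2[sel] <= 0)) {
    abort("`t1` and `t2` must be positive wherever `rho` > 0.")
  }
  spacing <- rep_len(spacing, 3)
  structure(list(rho = rho, t1 = t1, t2 = t2, spacing = spacing),
            class = "mri_phantom")
}

# centered voxel-center coordinates (mm) for one dimension
.centered_coords <- function(n, spacing) {
  (seq_len(n) - 1 - floor(n / 2)) * spacing
}

#' Voxel coordinates of a phantom or image volume
#'
#' @param x an `mri_phantom` or `image_volume`.
#' @return tibble `x, y, z` (mm) in array order (first index fastest).
#' @export
voxel_coords <- function(x) {
  d <- dim(x$rho %||% x$voxels)
  g <- expand.grid(
    x = .centered_coords(d[1], x$spacing[1]),
    y = .centered_coords(d[2], x$spacing[2]),
    z = .centered_coords(d[3], x$spacing[3])
  )
  as_tibble(g)
}

#' Water-tube grid phantom
#'
#' A 7 x 7 rectangular grid of water-filled tubes with the four corner
#' positions empty (45 tubes), tube axes along z. The default geometry --
#' 8-mm diameter, 35-mm length, 17-mm pitch -- matches the resolution
#' phantom used for distortion mapping.
#'
#' @param tube_diameter_mm,tube_length_mm,grid_pitch_mm tube geometry (mm).
#' @param voxel_mm isotropic voxel size (mm); must be at most a quarter of
#'   the tube diameter.
#' @param grid_n tubes per side of the square grid.
#' @param margin_mm empty border around the grid (mm).
#' @param t1_ms,t2_ms relaxation of the tube water (ms).
#' @return an `mri_phantom`.
#' @export
tube_grid_phantom <- function(tube_diameter_mm = 8, tube_length_mm = 35,
                              grid_pitch_mm = 17, voxel_mm = 2, grid_n = 7,
                              margin_mm = 12, t1_ms = 2500, t2_ms = 2000) {
  if (grid_pitch_mm <= tube_diameter_mm) {
    abort("tubes overlap: grid pitch must exceed the tube diameter.")
  }
  if (voxel_mm > tube_diameter_mm / 4) {
    abort("voxel must be at most tube_diameter / 4 to resolve the tubes.")
  }
  half_extent <- (grid_n - 1) / 2 * grid_pitch_mm + tube_diameter_mm / 2 + margin_mm
  nxy <- 2L * ceiling(half_extent / voxel_mm)
  nz <- 2L * ceiling((tube_length_mm / 2 + margin_mm) / voxel_mm)
  cx <- .centered_coords(nxy, voxel_mm)
  cz <- .centered_coords(nz, voxel_mm)
  centers <- tube_grid_centers(grid_pitch_mm, grid_n)
  rho <- array(0, c(nxy, nxy, nz))
  inz <- abs(cz) <= tube_length_mm / 2
  r <- tube_diameter_mm / 2
  # partial-volume rasterization: boundary voxels get the fractional disk
  # coverage from a 4 x 4 sub-voxel sample
  sub <- (seq_len(4) - 2.5) / 4 * voxel_mm
  for (t in seq_len(nrow(centers))) {
    d2 <- outer((cx - centers$x[t])^2, (cx - centers$y[t])^2, "+")
    disk <- matrix(0, nxy, nxy)
    disk[d2 <= (r - voxel_mm)^2] <- 1
    edge <- which(d2 > (r - voxel_mm)^2 & d2 < (r + voxel_mm)^2, arr.ind = TRUE)
    if (nrow(edge)) {
      for (e in seq_len(nrow(edge))) {
        ex <- cx[edge[e, 1]] - centers$x[t]
        ey <- cx[edge[e, 2]] - centers$y[t]
        d2s <- outer((ex + sub)^2, (ey + sub)^2, "+")
        disk[edge[e, 1], edge[e, 2]] <- mean(d2s <= r^2)
      }
    }
    rho[, , inz] <- rho[, , inz] + array(disk, c(nxy, nxy, sum(inz)))
  }
  rho <- pmin(rho, 1)
  mri_phantom(rho, array(t1_ms, dim(rho)), array(t2_ms, dim(rho)), voxel_mm)
}

#' @rdname tube_grid_phantom
#' @return `tube_grid_centers()`: tibble of the 45 tube centers (mm) in the
#'   x-y plane.
#' @export
tube_grid_centers <- function(grid_pitch_mm = 17, grid_n = 7) {
  pos <- (seq_len(grid_n) - (grid_n + 1) / 2) * grid_pitch_mm
  g <- expand.grid(x = pos, y = pos)
  corner <- (abs(g$x) == max(abs(pos))) & (abs(g$y) == max(abs(pos)))
  as_tibble(g[!corner, ])
}

#' Brain and knee tissue phantoms
#'
#' `"brain"`: an ellipsoid of brain tissue (T1 500 ms / T2 250 ms) with two
#' interior CSF ventricle compartments (T1 1750 ms; T2 = 0.9 T1, since
#' T1 and T2 converge for mobile liquids at very low field). `"knee"`:
#' concentric cylinders of cartilage (T1/T2 70/20 ms), muscle (200/47 ms)
#' and fat (140/84 ms).
#'
#' @param kind `"brain"` or `"knee"`.
#' @param n grid size (isotropic n^3 array).
#' @param voxel_mm voxel size (mm).
#' @param ventricle_scale relative size of the CSF ventricles (0 gives a
#'   pure single-tissue ellipsoid).
#' @return an `mri_phantom`.
#' @export
tissue_phantom <- function(kind = c("brain", "knee"), n = 48, voxel_mm = 4,
                           ventricle_scale = 1) {
  kind <- match.arg(kind)
  cc <- .centered_coords(n, voxel_mm)
  X <- array(rep(cc, times = n * n), c(n, n, n))
  Y <- array(rep(rep(cc, each = n), times = n), c(n, n, n))
  Z <- array(rep(cc, each = n * n), c(n, n, n))
  rho <- array(0, c(n, n, n))
  t1 <- array(1, c(n, n, n))
  t2 <- array(1, c(n, n, n))
  ext <- n * voxel_mm / 2
  if (kind == "brain") {
    ax <- c(0.65, 0.8, 0.55) * ext
    inside <- (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2 <= 1
    rho[inside] <- 1
    t1[inside] <- 500
    t2[inside] <- 250
    if (ventricle_scale > 0) {
      vax <- c(0.12, 0.3, 0.12) * ext * ventricle_scale
      for (s in c(-1, 1)) {
        vent <- ((X - s * 0.18 * ext) / vax[1])^2 + (Y / vax[2])^2 +
          (Z / vax[3])^2 <= 1
        t1[vent] <- 1750
        t2[vent] <- 0.9 * 1750
        rho[vent] <- 1
      }
    }
  } else {
    r <- sqrt(Y^2 + Z^2)
    lim <- 0.85 * ext
    cart <- r <= 0.25 * lim
    musc <- r > 0.25 * lim & r <= 0.75 * lim
    fat <- r > 0.75 * lim & r <= lim
    rho[cart | musc | fat] <- 1
    t1[cart] <- 70;  t2[cart] <- 20
    t1[musc] <- 200; t2[musc] <- 47
    t1[fat] <- 140;  t2[fat] <- 84
  }
  mri_phantom(rho, t1, t2, voxel_mm)
}

#' Steady-state TSE contrast weight
#'
#' Signal weight of a tissue under saturation-recovery
#' (`(1 - exp(-TR/T1)) exp(-TEeff/T2)`) or inversion-recovery
#' (`|1 - 2 exp(-TI/T1) + exp(-TR/T1)| exp(-TEeff/T2)`) turbo-spin-echo
#' imaging; the effective TE follows from the protocol's k-space ordering.
#'
#' @param t1,t2 relaxation times (ms); vectorized.
#' @param p a [tse_params()] (needs `ti` for inversion recovery).
#' @param mode `"saturation_recovery"` or `"inversion_recovery"`.
#' @param effective_te override the effective TE (ms).
#' @return weight in `[0, 1]` (vector).
#' @export
contrast_weighting <- function(t1, t2, p,
                               mode = c("saturation_recovery",
                                        "inversion_recovery"),
                               effective_te = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(t1 > 0), all(t2 > 0))
  te_eff <- effective_te %||% echo_train_schedule(p)$effective_te
  rec <- if (mode == "saturation_recovery") {
    1 - exp(-p$tr / t1)
  } else {
    if (is.null(p$ti)) abort("inversion recovery needs `ti` in the protocol.")
    abs(1 - 2 * exp(-p$ti / t1) + exp(-p$tr / t1))
  }
  rec * exp(-te_eff / t2)
}

#' Acquisition simulation configuration
#'
#' @param noise_sd standard deviation of the additive complex white noise
#'   (per real/imag channel, same units as the signal).
#' @param seed RNG seed for the noise.
#' @param drift a [drift_model()] or `NULL`.
#' @param drift_granularity apply the drift frequency per `"shot"` (frozen
#'   at the excitation) or per `"sample"` (evaluated at each echo time).
#' @param include_t2_in_train apply per-echo T2 decay across the echo train.
#' @param contrast `NULL`, `"saturation_recovery"` or
#'   `"inversion_recovery"`: steady-state weighting applied to the phantom.
#' @return a list of class `acq_config`.
#' @export
acq_config <- function(noise_sd = 0, seed = 1, drift = NULL,
                       drift_granularity = c("shot", "sample"),
                       include_t2_in_train = FALSE, contrast = NULL) {
  drift_granularity <- match.arg(drift_granularity)
  stopifnot(noise_sd >= 0)
  structure(
    list(noise_sd = noise_sd, seed = as.integer(seed), drift = drift,
         drift_granularity = drift_granularity,
         include_t2_in_train = include_t2_in_train, contrast = contrast),
    class = "acq_config"
  )
}

#' Identity encoding maps for a phantom grid
#'
#' The maps a perfectly linear gradient set would produce: the voxel
#' coordinates themselves (in meters), with zero off-resonance.
#'
#' @param ph an `mri_phantom` (or `image_volume`).
#' @return list of class `encoding_maps` with arrays `gx, gy, gz` (m) and
#'   `delta_b0` (Hz).
#' @export
identity_encoding_maps <- function(ph) {
  d <- dim(ph$rho %||% ph$voxels)
  sp <- ph$spacing
  gx <- array(rep(.centered_coords(d[1], sp[1]), times = d[2] * d[3]), d) / 1000
  gy <- array(rep(rep(.centered_coords(d[2], sp[2]), each = d[1]),
                  times = d[3]), d) / 1000
  gz <- array(rep(.centered_coords(d[3], sp[3]), each = d[1] * d[2]), d) / 1000
  encoding_maps(gx, gy, gz)
}

#' Encoding maps container
#'
#' Per-voxel effective coordinates (m) of the three gradient coils plus an
#' off-resonance map (Hz), on the image grid.
#'
#' @param gx,gy,gz effective-coordinate arrays (m).
#' @param delta_b0 off-resonance array (Hz) or `NULL` for zero.
#' @return a list of class `encoding_maps`.
#' @export
encoding_maps <- function(gx, gy, gz, delta_b0 = NULL) {
  stopifnot(all(dim(gx) == dim(gy)), all(dim(gx) == dim(gz)))
  if (is.null(delta_b0)) delta_b0 <- array(0, dim(gx))
  stopifnot(all(dim(gx) == dim(delta_b0)))
  structure(list(gx = gx, gy = gy, gz = gz, delta_b0 = delta_b0),
            class = "encoding_maps")
}

#' Simulate Cartesian k-space acquisition under arbitrary encoding fields
#'
#' Forward model: every sample accumulates phase from the (possibly
#' nonlinear) encoding fields and the off-resonance map,
#' `s(k) = sum_r rho(r) w(r) exp(-i 2 pi (kx gx(r) + ky gy(r) + kz gz(r)
#' + (dB0(r) + drift(t)) t_samp))`, with `t_samp` the echo-centered readout
#' time. With identity maps and zero off-resonance this is exactly the
#' centered discrete Fourier transform of the weighted phantom, so
#' [ifft_recon()] inverts it.
#'
#' @param ph an `mri_phantom`.
#' @param maps an [encoding_maps()] on the phantom grid.
#' @param schedule an [echo_train_schedule()]; its protocol fixes matrix,
#'   FOV and bandwidth. The phantom grid may be finer than the acquisition
#'   matrix.
#' @param cfg an [acq_config()].
#' @return a list of class `kspace_data`: complex `samples` array
#'   (readout x phase1 x phase2), logical `mask`, `schedule`, `dwell_s`,
#'   `params`.
#' @export
simulate_acquisition <- function(ph, maps, schedule, cfg = acq_config()) {
  stopifnot(inherits(ph, "mri_phantom"), inherits(maps, "encoding_maps"),
            inherits(schedule, "encode_schedule"), inherits(cfg, "acq_config"))
  if (!all(dim(ph$rho) == dim(maps$gx))) {
    abort("encoding maps and phantom grids do not match.")
  }
  p <- schedule$params
  nx <- p$matrix[1]; n1 <- p$matrix[2]; n2 <- p$matrix[3]
  fov_m <- p$fov / 1000
  kx <- .centered_coords(nx, 1) / fov_m[1]          # cycles / m
  dwell <- 1 / p$bandwidth
  t_samp <- .centered_coords(nx, 1) * dwell          # s, echo-centered
  sel <- which(ph$rho > 0)
  w <- ph$rho[sel]
  if (!is.null(cfg$contrast)) {
    te_eff <- if (cfg$include_t2_in_train) 0 else NULL
    w <- w * contrast_weighting(ph$t1[sel], ph$t2[sel], p, cfg$contrast,
                                effective_te = te_eff)
  }
  gx <- maps$gx[sel]; gy <- maps$gy[sel]; gz <- maps$gz[sel]
  db0 <- maps$delta_b0[sel]
  A <- exp(-2i * pi * (outer(kx, gx) + outer(t_samp, db0)))  # nx x nvox
  e <- schedule$entries
  ky <- e$k1 / fov_m[2]
  kz <- e$k2 / fov_m[3]
  drift_hz <- if (is.null(cfg$drift)) {
    rep(0, nrow(e))
  } else {
    tsh <- if (cfg$drift_granularity == "shot") (e$shot - 1) * p$tr else e$t_ms
    cfg$drift$rate_hz_per_hour * (tsh / 1000) / 3600
  }
  samples <- array(0i, c(nx, n1, n2))
  groups <- if (cfg$include_t2_in_train) split(seq_len(nrow(e)), e$echo) else
    list(seq_len(nrow(e)))
  for (g in groups) {
    wg <- if (cfg$include_t2_in_train) {
      w * exp(-(e$echo[g[1]] * p$te) / ph$t2[sel])
    } else w
    chunk <- max(1L, floor(4e6 / length(sel)))
    for (s0 in seq(1, length(g), by = chunk)) {
      li <- g[seq(s0, min(s0 + chunk - 1L, length(g)))]
      E <- exp(-2i * pi * (outer(gy, ky[li]) + outer(gz, kz[li])))  # nvox x nl
      S <- A %*% (wg * E)                                           # nx x nl
      D <- exp(-2i * pi * outer(t_samp, drift_hz[li]))
      S <- S * D
      i1 <- e$k1[li] + floor(n1 / 2) + 1L
      i2 <- e$k2[li] + floor(n2 / 2) + 1L
      samples[cbind(rep(seq_len(nx), length(li)),
                    rep(i1, each = nx), rep(i2, each = nx))] <- as.vector(S)
    }
  }
  mask <- array(FALSE, c(n1, n2))
  mask[cbind(e$k1 + floor(n1 / 2) + 1L, e$k2 + floor(n2 / 2) + 1L)] <- TRUE
  if (cfg$noise_sd > 0) {
    samples <- .with_seed(cfg$seed, {
      idx <- which(array(rep(mask, each = nx), dim(samples)))
      noise <- complex(real = rnorm(length(idx), sd = cfg$noise_sd),
                       imaginary = rnorm(length(idx), sd = cfg$noise_sd))
      samples[idx] <- samples[idx] + noise
      samples
    })
  }
  structure(
    list(samples = samples, mask = mask, schedule = schedule,
         dwell_s = dwell, params = p),
    class = "kspace_data"
  )
}
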