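#' Turbo-spin-echo protocol parameters
#'
#' Parameter container in the units the protocols are quoted in: mm for the
#' field of view, ms for times, Hz for the total readout bandwidth. The
#' first matrix/FOV dimension is the frequency-encoding (readout) axis; the
#' other two are phase encodes.
#'
#' @param fov 3-vector FOV (mm): readout, phase1, phase2.
#' @param matrix 3-vector acquisition matrix.
#' @param tr repetition time (ms).
#' @param te echo spacing (ms).
#' @param etl echo train length (echoes per excitation).
#' @param ti inversion time (ms) or `NULL`.
#' @param bandwidth total readout bandwidth (Hz).
#' @param ordering `"center_out"` (k-space center on the first echo) or
#'   `"linear_low_high"` (phase encodes swept low to high, center mid-train).
#' @param elliptical restrict the phase-encode plane to the inscribed
#'   ellipse.
#' @return a list of class `tse_params`.
#' @examples
#' tse_params(fov = c(160, 192, 256), matrix = c(40, 48, 64), tr = 3000,
#'            te = 20, etl = 40, ordering = "linear_low_high")
#' @export
tse_params <- function(fov = c(256, 256, 256), matrix = c(128, 128, 128),
                       tr = 115, te = 15, etl = 3, ti = NULL,
                       bandwidth = 20e3,
                       ordering = c("center_out", "linear_low_high"),
                       elliptical = TRUE) {
  ordering <- match.arg(ordering)
  matrix <- as.integer(matrix)
  stopifnot(length(fov) == 3, length(matrix) == 3, all(matrix >= 1),
            etl >= 1, bandwidth > 0, tr > 0, te > 0)
  if (te * etl >= tr) abort("echo train (te * etl) must fit inside tr.")
  structure(
    list(fov = fov, matrix = matrix, tr = tr, te = te, etl = as.integer(etl),
         ti = ti, bandwidth = bandwidth, ordering = ordering,
         elliptical = elliptical),
    class = "tse_params"
  )
}

#' Elliptical phase-encode mask
#'
#' Centered integer indices `i in [-n1/2, n1/2)`, `j in [-n2/2, n2/2)` are
#' included when `(i/(n1/2))^2 + (j/(n2/2))^2 <= 1`. The included fraction
#' tends to `pi/4` for large matrices -- the scan-time saving of elliptical
#' coverage.
#'
#' @param n1,n2 phase-encode matrix sizes.
#' @param elliptical if `FALSE`, everything is included.
#' @return a tibble `k1, k2, included` over all centered index pairs.
#' @export
elliptical_mask <- function(n1, n2, elliptical = TRUE) {
  stopifnot(n1 >= 1, n2 >= 1)
  i <- seq.int(-floor(n1 / 2), ceiling(n1 / 2) - 1L)
  j <- seq.int(-floor(n2 / 2), ceiling(n2 / 2) - 1L)
  g <- expand.grid(k1 = i, k2 = j)
  inc <- if (!elliptical) {
    rep(TRUE, nrow(g))
  } else if (n1 == 1 && n2 == 1) {
    rep(TRUE, nrow(g))
  } else {
    a <- max(n1 / 2, 0.5); b <- max(n2 / 2, 0.5)
    (g$k1 / a)^2 + (g$k2 / b)^2 <= 1 + 1e-12
  }
  tibble(k1 = g$k1, k2 = g$k2, included = inc)
}

#' Total scan time of a TSE protocol
#'
#' `shots = ceiling(n_encodes / etl)` excitations, one TR each:
#' `time = shots * tr`. Encode count honours the elliptical mask. Inversion
#' and dummy shots are excluded.
#'
#' @param p a [tse_params()].
#' @return scan time (s).
#' @examples
#' # 128 x 128 phase encodes, ETL 3, TR 130 ms -> 710.06 s (11 min 50 s)
#' scan_time(tse_params(matrix = c(128, 128, 128), tr = 130, te = 10,
#'                      etl = 3, elliptical = FALSE))
#' @export
scan_time <- function(p) {
  stopifnot(inherits(p, "tse_params"))
  m <- elliptical_mask(p$matrix[2], p$matrix[3], p$elliptical)
  n_enc <- sum(m$included)
  shots <- ceiling(n_enc / p$etl)
  shots * p$tr / 1000
}

#' Echo-train encode schedule and effective TE
#'
#' Assigns every masked (k1, k2) phase-encode line to a shot and echo.
#' `center_out` sorts lines by elliptical radius so the k-space center is
#' read on echo 1 (effective TE = te); `linear_low_high` partitions lines
#' into `etl` contiguous bands in phase1 order so the center is read
#' mid-train (effective TE = (etl + 1)/2 * te). Refocusing pulses follow
#' the CPMG convention; alternating phase labels are recorded per echo.
#'
#' @param p a [tse_params()].
#' @return a list of class `encode_schedule`: `entries` (tibble `k1, k2,
#'   shot, echo, t_ms, rf_phase`), `effective_te` (ms), `shots`, `params`.
#' @export
echo_train_schedule <- function(p) {
  stopifnot(inherits(p, "tse_params"))
  m <- elliptical_mask(p$matrix[2], p$matrix[3], p$elliptical)
  lines <- m[m$included, c("k1", "k2")]
  n_enc <- nrow(lines)
  if (p$etl > n_enc) {
    abort(sprintf("etl (%d) exceeds the number of encodes (%d).", p$etl, n_enc))
  }
  shots <- ceiling(n_enc / p$etl)
  a <- max(p$matrix[2] / 2, 0.5); b <- max(p$matrix[3] / 2, 0.5)
  ord <- switch(p$ordering,
    center_out = order((lines$k1 / a)^2 + (lines$k2 / b)^2, lines$k1, lines$k2),
    linear_low_high = order(lines$k1, lines$k2)
  )
  lines <- lines[ord, ]
  rank <- seq_len(n_enc)
  echo <- (rank - 1L) %/% shots + 1L
  shot <- (rank - 1L) %% shots + 1L
  entries <- tibble(
    k1 = lines$k1, k2 = lines$k2, shot = shot, echo = echo,
    t_ms = (shot - 1) * p$tr + echo * p$te,
    rf_phase = ifelse(echo %% 2L == 1L, "+y", "-y")
  )
  eff_te <- switch(p$ordering,
    center_out = p$te,
    linear_low_high = (p$etl + 1) / 2 * p$te
  )
  structure(
    list(entries = entries, effective_te = eff_te, shots = shots, params = p),
    class = "encode_schedule"
  )
}

#' Main-field drift model
#'
#' Either a direct drift rate in Hz per hour, or a thermal path: frequency
#' sensitivity (Hz/degC) times a heating rate (degC/hour).
#'
#' @param rate_hz_per_hour drift rate (Hz/h).
#' @param sensitivity_hz_per_degc,degc_per_hour thermal path; used when
#'   `rate_hz_per_hour` is missing.
#' @return a list of class `drift_model`.
#' @export
drift_model <- function(rate_hz_per_hour = NULL,
                        sensitivity_hz_per_degc = NULL,
                        degc_per_hour = NULL) {
  if (is.null(rate_hz_per_hour)) {
    if (is.null(sensitivity_hz_per_degc) || is.null(degc_per_hour)) {
      abort("give `rate_hz_per_hour` or both thermal-path arguments.")
    }
    rate_hz_per_hour <- sensitivity_hz_per_degc * degc_per_hour
  }
  if (!is.finite(rate_hz_per_hour)) abort("drift rate must be finite.")
  structure(list(rate_hz_per_hour = rate_hz_per_hour), class = "drift_model")
}

#' Accumulated frequency drift over a scan
#'
#' @param model a [drift_model()].
#' @param duration_min scan duration (minutes).
#' @return frequency offset (Hz); e.g. 800 Hz/h over 12 min -> 160 Hz.
#' @export
drift_frequency <- function(model, duration_min) {
  stopifnot(inherits(model, "drift_model"), duration_min >= 0)
  model$rate_hz_per_hour * duration_min / 60
}

#' Point-spread-function and resolution arithmetic
#'
#' Combines the PSF broadening mechanisms of a low-field TSE acquisition in
#' the frequency-encoding direction: main-field drift over the scan
#' (`drift_hz` divided by the readout gradient strength in Hz/mm), the B0
#' linewidth relative to the per-pixel bandwidth, and T2 decay along the
#' echo train in the phase-encode direction (FWHM of the Fourier transform
#' of the echo-train weighting). The combined readout resolution adds the
#' voxel size and linewidth PSF in quadrature.
#'
#' @param p a [tse_params()].
#' @param linewidth_hz B0 inhomogeneity linewidth (FWHM of the FID
#'   spectrum, Hz).
#' @param drift_hz total drift over the acquisition (Hz).
#' @param tissue_t2 T2 used for the echo-train decay PSF (ms).
#' @param voxel_mm nominal voxel (mm); default `fov[1]/matrix[1]`.
#' @param pixel_bandwidth_hz per-pixel bandwidth (Hz); default
#'   `bandwidth/matrix[1]`.
#' @return a tibble with one row: `drift_broadening_mm`, `linewidth_psf_px`,
#'   `linewidth_psf_mm`, `combined_readout_mm`, `t2_psf_px`.
#' @export
resolution_report <- function(p, linewidth_hz, drift_hz, tissue_t2,
                              voxel_mm = NULL, pixel_bandwidth_hz = NULL) {
  stopifnot(inherits(p, "tse_params"), linewidth_hz >= 0, drift_hz >= 0,
            tissue_t2 > 0)
  voxel_mm <- voxel_mm %||% (p$fov[1] / p$matrix[1])
  pixel_bandwidth_hz <- pixel_bandwidth_hz %||% (p$bandwidth / p$matrix[1])
  hz_per_mm <- p$bandwidth / p$fov[1]
  drift_broadening_mm <- drift_hz / hz_per_mm
  linewidth_psf_px <- linewidth_hz / pixel_bandwidth_hz
  linewidth_psf_mm <- linewidth_psf_px * voxel_mm
  combined <- sqrt(voxel_mm^2 + linewidth_psf_mm^2)
  tibble(
    drift_broadening_mm = drift_broadening_mm,
    linewidth_psf_px = linewidth_psf_px,
    linewidth_psf_mm = linewidth_psf_mm,
    combined_readout_mm = combined,
    t2_psf_px = .t2_train_psf_px(p, tissue_t2)
  )
}

# FWHM (in pixels of the phase1 axis) of the PSF caused by T2 decay across
# the echo train, from the actual echo-to-line assignment of the schedule.
.t2_train_psf_px <- function(p, tissue_t2) {
  sched <- echo_train_schedule(p)
  n1 <- p$matrix[2]
  w <- rep(0, n1)
  e <- sched$entries
  k_idx <- e$k1 + floor(n1 / 2) + 1L
  # average decay weight per phase1 line (collapse phase2)
  agg <- tapply(exp(-(e$echo * p$te) / tissue_t2), k_idx, mean)
  w[as.integer(names(agg))] <- agg
  pad <- 32L
  wz <- rep(0, n1 * pad)
  wz[seq_len(n1)] <- w
  psf <- abs(fft(wz))
  psf <- c(psf[(length(psf) / 2 + 1):length(psf)], psf[1:(length(psf) / 2)])
  .fwhm(psf) / pad
}

.fwhm <- function(y) {
  imax <- which.max(y)
  half <- y[imax] / 2
  left <- imax
  while (left > 1 && y[left - 1] > half) left <- left - 1
  l <- if (left == 1) 1 else
    left - 1 + (y[left - 1] - half) / (y[left - 1] - y[left])
  right <- imax
  while (right < length(y) && y[right + 1] > half) right <- right + 1
  r <- if (right == length(y)) length(y) else
    right + (y[right] - half) / (y[right] - y[right + 1])
  r - l
}
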