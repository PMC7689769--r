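#' Reconstructed image volume
#'
#' @param voxels 3-D array (magnitude, or complex when requested).
#' @param spacing voxel size (mm), length 1 or 3.
#' @param note free-text orientation/provenance note.
#' @return a list of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, note = "") {
  stopifnot(length(dim(voxels)) == 3)
  structure(list(voxels = voxels, spacing = rep_len(spacing, 3), note = note),
            class = "image_volume")
}

# centered n-dimensional DFT via FFT plus per-dimension phase ramps.
# sign = -1: forward (no normalization); sign = +1: inverse (1/N total).
# Index i maps to centered index i - 1 - floor(N/2); frequency likewise.
.centered_dft <- function(x, sign) {
  d <- dim(x)
  ph <- lapply(d, function(n) {
    c0 <- floor(n / 2)
    exp(-sign * 2i * pi * c0 * (seq_len(n) - 1) / n)
  })
  const <- prod(vapply(d, function(n) {
    c0 <- floor(n / 2)
    exp(sign * 2i * pi * c0^2 / n)
  }, complex(1)))
  P <- array(1 + 0i, d)
  P <- sweep(P, 1, ph[[1]], "*")
  if (length(d) >= 2) P <- sweep(P, 2, ph[[2]], "*")
  if (length(d) >= 3) P <- sweep(P, 3, ph[[3]], "*")
  y <- P * fft(P * x, inverse = sign > 0) * const
  if (sign > 0) y <- y / prod(d)
  y
}

#' Apodize k-space with a sine-bell-squared window
#'
#' Separable window `w(i) = sin^2(pi i / N)` (0-based natural index, i.e.
#' `cos^2(pi k / N)` in centered k index) along every non-trivial dimension.
#' The window peaks exactly at the k-space center index and is symmetric
#' under k negation, so Hermitian data stay Hermitian. Trades ringing for a
#' known, slight PSF broadening.
#'
#' @param k a `kspace_data`.
#' @param window `"sine_bell_squared"` or `"none"`.
#' @return the filtered `kspace_data`; the window value at the k-space
#'   center is recorded in attribute `dc_scale`.
#' @export
window_filter <- function(k, window = c("sine_bell_squared", "none")) {
  window <- match.arg(window)
  stopifnot(inherits(k, "kspace_data"))
  if (window == "none") return(k)
  d <- dim(k$samples)
  wins <- lapply(d, function(n) {
    if (n == 1) return(1)
    sin(pi * (seq_len(n) - 1) / n)^2
  })
  s <- k$samples
  s <- sweep(s, 1, wins[[1]], "*")
  s <- sweep(s, 2, wins[[2]], "*")
  s <- sweep(s, 3, wins[[3]], "*")
  k$samples <- s
  attr(k, "dc_scale") <- prod(vapply(seq_along(d), function(j) {
    if (d[j] == 1) 1 else wins[[j]][floor(d[j] / 2) + 1]
  }, numeric(1)))
  k
}

#' Inverse-FFT image reconstruction
#'
#' Centered three-dimensional inverse discrete Fourier transform of the
#' (zero-filled) k-space array; the standard reconstruction when the
#' encoding fields are linear.
#'
#' @param k a `kspace_data`.
#' @param magnitude return the magnitude image (default) or the complex
#'   volume.
#' @return an [image_volume()] on the nominal voxel grid
#'   (`fov / matrix` mm).
#' @export
ifft_recon <- function(k, magnitude = TRUE) {
  stopifnot(inherits(k, "kspace_data"))
  img <- .centered_dft(k$samples, sign = +1)
  vox <- if (magnitude) abs(img) else img
  image_volume(vox, spacing = k$params$fov / k$params$matrix,
               note = "ifft reconstruction")
}

#' Conjugate-phase reconstruction with gradient-nonlinearity and
#' off-resonance correction
#'
#' Replaces the inverse FFT by the direct sum
#' `rho(r) = sum_k s(k) exp(+i 2 pi (kx Gx(r) + ky Gy(r) + kz Gz(r)
#' + dB0(r) t))`, where `Gx, Gy, Gz` are the simulated encoding maps of the
#' actual coils (effective coordinates from Biot-Savart field maps), and
#' the off-resonance term multiplies the echo-centered readout time `t` of
#' each sample. With identity maps and zero off-resonance this reduces
#' exactly to [ifft_recon()]. The correction degrades where the encoding
#' field folds over (beyond gradient reversal points); a warning is issued
#' when maps exceed half the FOV.
#'
#' @param k a `kspace_data`.
#' @param maps an [encoding_maps()] on the output image grid (dimensions
#'   equal to the acquisition matrix).
#' @param magnitude return magnitude (default) or complex volume.
#' @return an [image_volume()].
#' @export
conjugate_phase_recon <- function(k, maps, magnitude = TRUE) {
  stopifnot(inherits(k, "kspace_data"), inherits(maps, "encoding_maps"))
  p <- k$params
  d <- dim(k$samples)
  if (!all(dim(maps$gx) == d)) {
    abort("encoding maps must be on the output image grid (acquisition matrix).")
  }
  fov_m <- p$fov / 1000
  if (max(abs(maps$gx)) > fov_m[1] / 2 + 1e-9 ||
      max(abs(maps$gy)) > fov_m[2] / 2 + 1e-9 ||
      max(abs(maps$gz)) > fov_m[3] / 2 + 1e-9) {
    warn(paste0("encoding maps exceed half the FOV; the conjugate-phase ",
                "correction is unreliable in fold-over regions."))
  }
  nx <- d[1]; n1 <- d[2]; n2 <- d[3]
  kx <- .centered_coords(nx, 1) / fov_m[1]
  ky <- .centered_coords(n1, 1) / fov_m[2]
  kz <- .centered_coords(n2, 1) / fov_m[3]
  t_samp <- .centered_coords(nx, 1) * k$dwell_s
  nvox <- prod(d)
  gx <- as.vector(maps$gx); gy <- as.vector(maps$gy); gz <- as.vector(maps$gz)
  db0 <- as.vector(maps$delta_b0)
  out <- complex(nvox)
  chunk <- max(1L, floor(2e6 / max(n1 * n2, nx)))
  for (v0 in seq(1, nvox, by = chunk)) {
    vi <- seq(v0, min(v0 + chunk - 1L, nvox))
    Ey <- exp(2i * pi * outer(gy[vi], ky))             # nv x n1
    Ez <- exp(2i * pi * outer(gz[vi], kz))             # nv x n2
    Ax <- exp(2i * pi * (outer(gx[vi], kx) + outer(db0[vi], t_samp)))  # nv x nx
    acc <- complex(length(vi))
    for (j in seq_len(nx)) {
      inner <- rowSums((Ey %*% matrix(k$samples[j, , ], n1, n2)) * Ez)
      acc <- acc + Ax[, j] * inner
    }
    out[vi] <- acc
  }
  img <- array(out / nvox, d)
  vox <- if (magnitude) abs(img) else img
  image_volume(vox, spacing = p$fov / p$matrix,
               note = "conjugate-phase reconstruction")
}

#' Remove main-field drift phase from k-space
#'
#' Multiplies every sample by the conjugate of the drift phase it picked up,
#' `exp(+i 2 pi df(t_shot) t_samp)`, with `df` from the drift model and
#' `t_samp` the echo-centered readout time -- the simple k-space phase shift
#' that undoes slow B0 drift.
#'
#' @param k a `kspace_data`.
#' @param model a [drift_model()].
#' @param granularity evaluate the drift per `"shot"` or per `"sample"`
#'   (at each echo time).
#' @return the corrected `kspace_data`.
#' @export
drift_phase_correction <- function(k, model,
                                   granularity = c("shot", "sample")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(k, "kspace_data"), inherits(model, "drift_model"))
  p <- k$params
  e <- k$schedule$entries
  nx <- dim(k$samples)[1]
  t_samp <- .centered_coords(nx, 1) * k$dwell_s
  tsh <- if (granularity == "shot") (e$shot - 1) * p$tr else e$t_ms
  drift_hz <- model$rate_hz_per_hour * (tsh / 1000) / 3600
  i1 <- e$k1 + floor(p$matrix[2] / 2) + 1L
  i2 <- e$k2 + floor(p$matrix[3] / 2) + 1L
  for (l in seq_len(nrow(e))) {
    k$samples[, i1[l], i2[l]] <- k$samples[, i1[l], i2[l]] *
      exp(2i * pi * drift_hz[l] * t_samp)
  }
  k
}

#' Geometric-distortion metrics from detected blob centroids
#'
#' Thresholds the image at half its maximum, labels 6-connected components,
#' computes intensity-weighted centroids and matches them to the reference
#' positions by iteratively pairing the globally closest (blob, reference)
#' couple. Reports the RMS position error and a per-blob table.
#'
#' @param img an [image_volume()].
#' @param reference_centers matrix or tibble of reference positions (mm,
#'   columns x, y, z; a 2-column input is padded with z = 0).
#' @param threshold detection threshold relative to the image maximum.
#' @return list of class `distortion_metrics`: `rms_mm`, `n_detected`,
#'   `n_reference`, `per_blob` tibble (`x, y, z, ref_x, ref_y, ref_z,
#'   error_mm`).
#' @export
distortion_metrics <- function(img, reference_centers, threshold = 0.5) {
  stopifnot(inherits(img, "image_volume"))
  ref <- as.matrix(as.data.frame(reference_centers))
  if (ncol(ref) == 2) ref <- cbind(ref, 0)
  v <- img$voxels
  d <- dim(v)
  thr <- threshold * max(v)
  if (!is.finite(thr) || thr <= 0) abort("image contains no detectable signal.")
  sel <- which(v > thr)
  if (!length(sel)) abort("no voxels above the detection threshold.")
  labels <- .label_components(sel, d)
  cx <- .centered_coords(d[1], img$spacing[1])
  cy <- .centered_coords(d[2], img$spacing[2])
  cz <- .centered_coords(d[3], img$spacing[3])
  ijk <- arrayInd(sel, d)
  blobs <- tibble(
    lab = labels, w = v[sel],
    x = cx[ijk[, 1]], y = cy[ijk[, 2]], z = cz[ijk[, 3]]
  ) |>
    group_by(.data$lab) |>
    summarise(x = sum(.data$x * .data$w) / sum(.data$w),
              y = sum(.data$y * .data$w) / sum(.data$w),
              z = sum(.data$z * .data$w) / sum(.data$w), .groups = "drop")
  nb <- nrow(blobs); nr <- nrow(ref)
  if (nb != nr) {
    warn(sprintf("detected %d blobs but %d references; matching the subset.",
                 nb, nr))
  }
  D <- outer(seq_len(nb), seq_len(nr), Vectorize(function(i, j) {
    sqrt((blobs$x[i] - ref[j, 1])^2 + (blobs$y[i] - ref[j, 2])^2 +
           (blobs$z[i] - ref[j, 3])^2)
  }))
  pairs <- NULL
  Dw <- D
  for (m in seq_len(min(nb, nr))) {
    ij <- arrayInd(which.min(Dw), dim(Dw))
    pairs <- rbind(pairs, c(ij[1], ij[2], D[ij[1], ij[2]]))
    Dw[ij[1], ] <- Inf
    Dw[, ij[2]] <- Inf
  }
  per_blob <- tibble(
    x = blobs$x[pairs[, 1]], y = blobs$y[pairs[, 1]], z = blobs$z[pairs[, 1]],
    ref_x = ref[pairs[, 2], 1], ref_y = ref[pairs[, 2], 2],
    ref_z = ref[pairs[, 2], 3], error_mm = pairs[, 3]
  )
  structure(
    list(rms_mm = sqrt(mean(per_blob$error_mm^2)), n_detected = nb,
         n_reference = nr, per_blob = per_blob),
    class = "distortion_metrics"
  )
}

# 6-connected component labels of the selected linear indices
.label_components <- function(sel, d) {
  pos <- arrayInd(sel, d)
  id <- setNames(seq_along(sel), paste(pos[, 1], pos[, 2], pos[, 3]))
  edges <- NULL
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb <- sweep(pos, 2, off, "+")
    key <- paste(nb[, 1], nb[, 2], nb[, 3])
    hit <- !is.na(id[key])
    if (any(hit)) edges <- rbind(edges, cbind(which(hit), id[key[hit]]))
  }
  if (is.null(edges)) return(seq_along(sel))
  g <- igraph::graph_from_edgelist(
    matrix(as.integer(edges), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(sel) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(sel)]
}
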