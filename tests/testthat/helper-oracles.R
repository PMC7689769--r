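# Independent oracles used across the suite. These deliberately avoid the
# package's own field/DFT code paths.

# --- exact field of a uniformly magnetized cuboid (surface-charge model) ---
# Magnet occupies [x1,x2] x [y1,y2] x [z1,z2], magnetization M (A/m) along z.
# Closed form from integrating the charged z-faces; Bz uses atan2 terms,
# Bx/By log terms.
cuboid_field_exact <- function(p, M, x1, x2, y1, y2, z1, z2) {
  xs <- c(x1, x2); ys <- c(y1, y2); zs <- c(z1, z2)
  bx <- by <- bz <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    sgn <- (-1)^(i + j + k)
    dx <- p[1] - xs[i]; dy <- p[2] - ys[j]; dz <- p[3] - zs[k]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    bz <- bz - sgn * atan2(dx * dy, dz * r)
    bx <- bx + sgn * log(r + dy)
    by <- by + sgn * log(r + dx)
  }
  -1e-7 * M * c(bx, by, bz)
}

# volume-subdivision cross-check: cube as n^3 point dipoles
cuboid_field_subdivided <- function(p, Br, edge, n = 12) {
  h <- edge / n
  cc <- (seq_len(n) - (n + 1) / 2) * h
  g <- expand.grid(x = cc, y = cc, z = cc)
  m_each <- Br * h^3 / (4e-7 * pi)
  B <- c(0, 0, 0)
  for (r in seq_len(nrow(g))) {
    d <- p - c(g$x[r], g$y[r], g$z[r])
    rr <- sqrt(sum(d^2))
    m <- c(0, 0, m_each)
    B <- B + 1e-7 * (3 * sum(m * d) * d / rr^5 - m / rr^3)
  }
  B
}

# --- off-axis circular loop field via complete elliptic integrals (AGM) ---
elliptic_KE <- function(m) {
  # AGM for K(m) and E(m), parameter m = k^2
  a <- 1; b <- sqrt(1 - m); c <- sqrt(m)
  s <- c^2 / 2; pw <- 1
  for (it in 1:60) {
    an <- (a + b) / 2; bn <- sqrt(a * b); cn <- (a - b) / 2
    a <- an; b <- bn
    pw <- pw * 2
    s <- s + pw * cn^2 / 2
    if (cn < 1e-16) break
  }
  K <- pi / (2 * a)
  list(K = K, E = K * (1 - s))
}

loop_field_exact <- function(R, I, rho, z) {
  # field of a circular loop of radius R in the plane z = 0, axis z;
  # returns c(B_rho, B_z)
  if (rho < 1e-12) {
    return(c(0, 2e-7 * pi * I * R^2 / (R^2 + z^2)^1.5))
  }
  m <- 4 * R * rho / ((R + rho)^2 + z^2)
  ke <- elliptic_KE(m)
  pref <- 2e-7 * I / sqrt((R + rho)^2 + z^2)
  Brho <- pref * (z / rho) *
    (-ke$K + (R^2 + rho^2 + z^2) / ((R - rho)^2 + z^2) * ke$E)
  Bz <- pref * (ke$K + (R^2 - rho^2 - z^2) / ((R - rho)^2 + z^2) * ke$E)
  c(Brho, Bz)
}

# --- brute-force centered DFT forward model (independent of the package) ---
brute_force_kspace <- function(rho, spacing_mm, fov_mm, kidx) {
  # rho: 3d array; kidx: data frame with centered indices jx, j1, j2
  d <- dim(rho)
  cc <- function(n, sp) (seq_len(n) - 1 - floor(n / 2)) * sp / 1000
  xs <- cc(d[1], spacing_mm[1]); ys <- cc(d[2], spacing_mm[2])
  zs <- cc(d[3], spacing_mm[3])
  sel <- which(rho > 0, arr.ind = TRUE)
  w <- rho[rho > 0]
  px <- xs[sel[, 1]]; py <- ys[sel[, 2]]; pz <- zs[sel[, 3]]
  out <- complex(nrow(kidx))
  for (r in seq_len(nrow(kidx))) {
    kx <- kidx$jx[r] / (fov_mm[1] / 1000)
    ky <- kidx$j1[r] / (fov_mm[2] / 1000)
    kz <- kidx$j2[r] / (fov_mm[3] / 1000)
    out[r] <- sum(w * exp(-2i * pi * (kx * px + ky * py + kz * pz)))
  }
  out
}

# --- exhaustive assignment (all permutations) for blob matching ---
brute_force_assignment_rms <- function(blobs, refs) {
  n <- nrow(blobs)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    d2 <- sum((blobs[, 1] - refs[p, 1])^2 + (blobs[, 2] - refs[p, 2])^2 +
                (blobs[, 3] - refs[p, 3])^2)
    if (d2 < best) best <- d2
  }
  sqrt(best / n)
}

# small deterministic GA config for toy problems
toy_ga <- function(seed = 1, pop = 60, gen = 60) {
  ga_config(population_size = pop, generations = gen, seed = seed,
            mutation_rate = 0.05)
}
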