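# Synthetic fixtures shared across the suite.  All are built in code at
# test time; lattice maps are ideal patterns with known symmetry, used
# as oracles for the gridness machinery.

# rate_map object from an explicit grid matrix (x bins along rows)
as_rate_map <- function(grid, bin_size = 0.05) {
  structure(
    list(
      grid = grid,
      occupancy = matrix(1, nrow(grid), ncol(grid)),
      x_edges = seq(0, by = bin_size, length.out = nrow(grid) + 1),
      y_edges = seq(0, by = bin_size, length.out = ncol(grid) + 1),
      bin_size = bin_size,
      extent = c(0, 0, nrow(grid) * bin_size, ncol(grid) * bin_size)
    ),
    class = "rate_map"
  )
}

# field map from Gaussian bumps at given centres
bump_map <- function(centers, extent = 3, bin_size = 0.05, width = 0.12) {
  xc <- seq(bin_size / 2, extent - bin_size / 2, by = bin_size)
  yc <- xc
  g <- matrix(0, length(xc), length(yc))
  for (i in seq_len(nrow(centers))) {
    g <- g + exp(-(outer((xc - centers[i, 1])^2, (yc - centers[i, 2])^2, "+")) /
                   (2 * width^2))
  }
  g
}

# ideal hexagonal lattice of Gaussian bumps
hex_lattice_map <- function(spacing = 0.5, extent = 3, bin_size = 0.05,
                            angle = 0, stretch_x = 1, width = 0.08) {
  a1 <- spacing * c(cos(angle), sin(angle))
  a2 <- spacing * c(cos(angle + pi / 3), sin(angle + pi / 3))
  ctr <- c(extent / 2, extent / 2)
  pts <- NULL
  for (i in -12:12) for (j in -12:12) {
    p <- ctr + i * a1 + j * a2
    if (all(p > -spacing) && all(p < extent + spacing)) pts <- rbind(pts, p)
  }
  pts[, 1] <- ctr[1] + (pts[, 1] - ctr[1]) * stretch_x
  as_rate_map(bump_map(pts, extent, bin_size, width), bin_size)
}

# ideal square lattice of Gaussian bumps
square_lattice_map <- function(spacing = 0.5, extent = 3, bin_size = 0.05,
                               width = 0.08) {
  ctr <- c(extent / 2, extent / 2)
  pts <- NULL
  for (i in -12:12) for (j in -12:12) {
    p <- ctr + c(i * spacing, j * spacing)
    if (all(p > -spacing) && all(p < extent + spacing)) pts <- rbind(pts, p)
  }
  as_rate_map(bump_map(pts, extent, bin_size, width), bin_size)
}

# naive O(N^4) Pearson autocorrelation, the Eq-by-the-book oracle
naive_autocorrelogram <- function(G, L, min_overlap = 5) {
  nr <- nrow(G); nc <- ncol(G)
  out <- matrix(NA_real_, 2 * L + 1, 2 * L + 1)
  for (tx in -L:L) for (ty in -L:L) {
    a <- c(); b <- c()
    for (i in 1:nr) for (j in 1:nc) {
      i2 <- i - tx; j2 <- j - ty
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
          !is.na(G[i, j]) && !is.na(G[i2, j2])) {
        a <- c(a, G[i, j]); b <- c(b, G[i2, j2])
      }
    }
    M <- length(a)
    if (M >= min_overlap) {
      num <- M * sum(a * b) - sum(a) * sum(b)
      den <- (M * sum(a^2) - sum(a)^2) * (M * sum(b^2) - sum(b)^2)
      if (den > 0) out[tx + L + 1, ty + L + 1] <- num / sqrt(den)
    }
  }
  out
}

# small arena + trajectory reused by several tests
tiny_square_traj <- function(duration = 60, seed = 42) {
  simulate_trajectory(env_square(1.8), duration, seed = seed)
}

# temporally correlated latent stream (AR(1), unit stationary variance
# scaled by sd): the LAHN's anti-Hebbian rule uses lag-1 response
# products, so its decorrelating force vanishes on temporally white
# input; fixtures mimic the slowly varying streams the network sees
ar1_stream <- function(n, k, sd, phi = 0.9) {
  e <- matrix(rnorm(n * k), n, k) %*% diag(sd, k, k)
  out <- matrix(0, n, k)
  out[1, ] <- e[1, ]
  for (t in 2:n) out[t, ] <- phi * out[t - 1, ] + sqrt(1 - phi^2) * e[t, ]
  out
}
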