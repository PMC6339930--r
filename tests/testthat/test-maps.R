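# Firing fields ---------------------------------------------------------------

test_that("firing-field thresholding keeps exactly the supra-threshold points", {
  traj <- tiny_square_traj(20)
  n <- nrow(traj)

  # constant response: nothing strictly above any quantile
  expect_equal(nrow(firing_field_map(traj, rep(2, n), 0.8)), 0)

  # indicator of the left half at quantile 0.5: exactly the left half
  resp <- as.numeric(traj$x < 0.9)
  ff <- firing_field_map(traj, resp, 1 - mean(resp) - 1e-9)
  expect_setequal(ff$t, traj$t[resp > 0])

  # random response: count matches a direct recount
  set.seed(1)
  r <- rnorm(n)
  eps <- quantile(r, 0.8, names = FALSE)
  expect_equal(nrow(firing_field_map(traj, r, 0.8)), sum(r > eps))

  expect_error(firing_field_map(traj, numeric(0)),
               class = "gridscape_error_empty_input")
})

# Rate maps -------------------------------------------------------------------

test_that("rate maps average responses per visited bin", {
  traj <- tiny_square_traj(30)
  n <- nrow(traj)

  rm_const <- rate_map(traj, rep(3, n), bin_size = 0.1, smoothing_sigma = 0)
  vals <- rm_const$grid[!is.na(rm_const$grid)]
  expect_true(all(abs(vals - 3) < 1e-12))

  # response = x coordinate: column means increase along x
  rm_x <- rate_map(traj, traj$x, bin_size = 0.1, smoothing_sigma = 0)
  colmeans <- rowMeans(rm_x$grid, na.rm = TRUE)
  expect_gt(cor(seq_along(colmeans), colmeans, use = "complete.obs"), 0.99)

  # synthetic Gaussian bump: map peak lands within one bin of the centre
  traj <- tiny_square_traj(240)
  bump <- exp(-((traj$x - 1.2)^2 + (traj$y - 0.6)^2) / (2 * 0.1^2))
  rm_b <- rate_map(traj, bump, bin_size = 0.1, smoothing_sigma = 0)
  pk <- which(rm_b$grid == max(rm_b$grid, na.rm = TRUE), arr.ind = TRUE)[1, ]
  pk_x <- rm_b$x_edges[pk[1]] + 0.05
  pk_y <- rm_b$y_edges[pk[2]] + 0.05
  expect_lt(abs(pk_x - 1.2), 0.15)
  expect_lt(abs(pk_y - 0.6), 0.15)

  traj <- tiny_square_traj(30)
  expect_error(rate_map(traj, rep(1, n), bin_size = 0),
               class = "gridscape_error_invalid_bin")
  # rectification clips negative responses
  rm_neg <- rate_map(traj, rep(-1, n), bin_size = 0.1, smoothing_sigma = 0)
  expect_true(all(rm_neg$grid[!is.na(rm_neg$grid)] == 0))
})

# Autocorrelogram -------------------------------------------------------------

test_that("autocorrelogram matches the naive per-lag Pearson oracle", {
  set.seed(2)
  G <- matrix(runif(16 * 16), 16)
  G[sample(256, 50)] <- NA
  rm <- as_rate_map(G, 0.1)
  ac <- autocorrelogram(rm, max_lag = 0.5, min_overlap = 5)
  oracle <- naive_autocorrelogram(G, ac$L, min_overlap = 5)
  ok <- !is.na(ac$r) & !is.na(oracle)
  expect_gt(sum(ok), 50)
  expect_lt(max(abs(ac$r[ok] - oracle[ok])), 1e-10)
  expect_identical(is.na(ac$r), is.na(oracle))
})

test_that("autocorrelogram basics: unit centre, lag symmetry, stripes", {
  m <- hex_lattice_map()
  ac <- autocorrelogram(m, max_lag = 1)
  expect_equal(ac$r[ac$L + 1, ac$L + 1], 1, tolerance = 1e-9)
  expect_equal(ac$r, ac$r[rev(seq_len(nrow(ac$r))), rev(seq_len(ncol(ac$r)))],
               tolerance = 1e-9)

  # stripe pattern: ridge at tau_x = wavelength, no 60-degree structure
  xc <- seq(0.025, 3, by = 0.05)
  stripes <- as_rate_map(matrix(rep(1 + cos(2 * pi * xc / 0.5), 60), 60), 0.05)
  acs <- autocorrelogram(stripes, max_lag = 1)
  lag_bins <- round(0.5 / 0.05)
  expect_gt(acs$r[acs$L + 1 + lag_bins, acs$L + 1], 0.95)
  # at half a wavelength the stripes anti-correlate
  expect_lt(acs$r[acs$L + 1 + round(lag_bins / 2), acs$L + 1], -0.9)

  # degenerate constant map: warns, everything masked
  flat <- as_rate_map(matrix(1, 20, 20), 0.05)
  expect_warning(acf <- autocorrelogram(flat, max_lag = 0.5), "degenerate")
  expect_true(all(is.na(acf$r)))
})

# Gridness --------------------------------------------------------------------

test_that("HGS separates hexagonal, square and ring patterns", {
  expect_gt(hgs(autocorrelogram(hex_lattice_map(), max_lag = 1)), 1)
  expect_lt(hgs(autocorrelogram(square_lattice_map(), max_lag = 1)), 0)

  # rotationally symmetric rings on a disc support: all rotations
  # equivalent, HGS ~ 0
  xc <- seq(0.025, 3, by = 0.05)
  rad <- sqrt(outer((xc - 1.5)^2, (xc - 1.5)^2, "+"))
  g <- 1 + cos(2 * pi * rad / 0.5)
  g[rad > 1.4] <- NA  # disc support keeps the overlap geometry isotropic
  rings <- as_rate_map(g, 0.05)
  expect_equal(as.numeric(hgs(autocorrelogram(rings, max_lag = 1))), 0,
               tolerance = 0.05)
})

test_that("noise degrades hexagonal gridness monotonically on average", {
  noise_levels <- seq(0, 1.8, length.out = 10)
  mean_scores <- vapply(noise_levels, function(nl) {
    mean(vapply(1:5, function(seed) {
      set.seed(seed)
      m <- hex_lattice_map()
      m$grid <- pmax(m$grid + matrix(rnorm(length(m$grid), sd = nl),
                                     nrow(m$grid)), 0)
      as.numeric(hgs(autocorrelogram(m, max_lag = 1)))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(noise_levels, mean_scores, method = "spearman"), -0.8)
  expect_lt(mean_scores[10], mean_scores[1])
})

test_that("HGS is invariant to lattice rotation and co-scaling", {
  base <- as.numeric(hgs(autocorrelogram(hex_lattice_map(angle = 0), max_lag = 1)))
  for (a in c(10, 25, 47)) {
    rot <- as.numeric(hgs(autocorrelogram(hex_lattice_map(angle = a * pi / 180),
                                          max_lag = 1)))
    expect_equal(rot, base, tolerance = 0.08)
  }
  # co-scale spacing and max_lag
  big <- as.numeric(hgs(autocorrelogram(
    hex_lattice_map(spacing = 0.75, extent = 4.5, bin_size = 0.075),
    max_lag = 1.5
  )))
  expect_equal(big, base, tolerance = 0.05)
})

test_that("ellipticity recovers circular and stretched rings", {
  expect_equal(ellipticity(autocorrelogram(hex_lattice_map(), max_lag = 1)), 1,
               tolerance = 0.05)
  stretched <- hex_lattice_map(stretch_x = 1.5, extent = 4)
  expect_equal(ellipticity(autocorrelogram(stretched, max_lag = 1.3)), 1.5,
               tolerance = 0.1)

  # two peaks only: undefined ellipse
  xc <- seq(0.025, 3, by = 0.05)
  two <- as_rate_map(bump_map(rbind(c(1.0, 1.5), c(2.0, 1.5), c(1.5, 1.5)),
                              3, 0.05), 0.05)
  expect_error(ellipticity(autocorrelogram(two, max_lag = 0.8)),
               class = "gridscape_error_undefined_ellipse")
})

test_that("half-map similarity behaves on symmetric and constant maps", {
  # mirror-symmetric map correlates perfectly across the cut
  g <- bump_map(rbind(c(0.8, 1.0), c(2.2, 1.0), c(0.8, 2.0), c(2.2, 2.0),
                      c(0.5, 1.5), c(2.5, 1.5)), 3, 0.05)
  expect_equal(half_map_similarity(as_rate_map(g, 0.05)), 1, tolerance = 1e-6)

  const <- as_rate_map(matrix(5, 30, 30), 0.05)
  expect_warning(s <- half_map_similarity(const), "constant")
  expect_true(is.na(s))

  # phase-shifted lattice: matches a brute-force correlation of the
  # extracted, reflected half arrays (nearest-to-cut rows first)
  m <- hex_lattice_map()
  s1 <- half_map_similarity(m)
  G <- m$grid
  k <- floor(nrow(G) / 2)
  left <- G[k:1, , drop = FALSE]
  right <- G[(k + 1):(2 * k), , drop = FALSE]
  expect_equal(s1, cor(as.vector(left), as.vector(right)), tolerance = 1e-9)
})

test_that("local and global gridness distinguish seamless and mismatched rooms", {
  env <- env_connected("square", "square", 1.8, 0.8, 0.4)
  traj <- simulate_trajectory(env, 900, seed = 21)
  lattice_resp <- function(x, y, angle) {
    k <- 2 * pi / 0.45
    dirs <- rbind(c(cos(angle), sin(angle)),
                  c(cos(angle + pi / 3), sin(angle + pi / 3)),
                  c(cos(angle + 2 * pi / 3), sin(angle + 2 * pi / 3)))
    pmax(cos(k * (x * dirs[1, 1] + y * dirs[1, 2])) +
         cos(k * (x * dirs[2, 1] + y * dirs[2, 2])) +
         cos(k * (x * dirs[3, 1] + y * dirs[3, 2])), 0)
  }
  seamless <- lattice_resp(traj$x, traj$y, 0.2)
  comp <- gridscape:::arena_compartment(env, traj$x, traj$y)
  mismatched <- ifelse(comp == "b",
                       lattice_resp(traj$x, traj$y, 0.2 + pi / 6),
                       lattice_resp(traj$x, traj$y, 0.2))
  lg_seam <- local_global_hgs(env, traj, seamless, bin_size = 0.02)
  lg_mis <- local_global_hgs(env, traj, mismatched, bin_size = 0.02)
  expect_gt(lg_seam$hgs_global, 0.5)
  expect_gt(lg_seam$hgs_global, lg_mis$hgs_global)
  expect_gt(lg_mis$hgs_local, lg_mis$hgs_global)

  # corridor-only samples: insufficient sampling in the rooms
  keep <- comp == "corridor"
  slim <- traj[keep, ]
  attr(slim, "dt") <- attr(traj, "dt")
  expect_error(local_global_hgs(env, slim, seamless[keep]),
               class = "gridscape_error_insufficient_sampling")

  expect_error(local_global_hgs(env_square(1), traj, seamless),
               class = "gridscape_error_invalid_shape")
})
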