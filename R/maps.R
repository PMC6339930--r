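# Firing-field maps, occupancy-normalised rate maps and spatial
# autocorrelograms.
#
# Rate maps bin the (rectified) response by position and average within
# bins; unvisited bins are NA and excluded from every correlation.  The
# default bin size of 0.01 arena units resolves the model's intrinsic
# spatial wavelength 2*pi/beta (~0.126 units at beta = 50; the first
# zero of the field autocorrelation falls at ~0.05 units and must span
# several bins).  The autocorrelogram is the Pearson correlation of the map
# with itself at every 2-D spatial lag, computed only over pixels where
# both copies are visited; lags with fewer than `min_overlap` shared
# pixels are masked.

#' Firing-field points
#'
#' Trajectory positions where the response exceeds a quantile threshold
#' (the "red dots" view of a neuron's firing field).
#'
#' @param traj Trajectory.
#' @param response Numeric response vector aligned with `traj`.
#' @param threshold_quantile Quantile of the response distribution used
#'   as threshold; points strictly above it are returned.
#' @return Tibble with `t`, `x`, `y`, `response`.
#' @export
firing_field_map <- function(traj, response, threshold_quantile = 0.8) {
  if (length(response) == 0) {
    abort("empty response", class = "gridscape_error_empty_input")
  }
  if (length(response) != nrow(traj)) {
    abort("response and trajectory lengths differ", class = "gridscape_error_shape")
  }
  eps <- stats::quantile(response, threshold_quantile, names = FALSE)
  keep <- response > eps
  tibble(t = traj$t[keep], x = traj$x[keep], y = traj$y[keep],
         response = response[keep])
}

# Core binning on bare coordinates (also used for half/compartment maps).
rate_map_xy <- function(x, y, response, bin_size, smoothing_sigma = 1,
                        rectify = TRUE, extent = NULL) {
  if (bin_size <= 0) {
    abort("bin_size must be positive", class = "gridscape_error_invalid_bin")
  }
  if (rectify) response <- pmax(response, 0)
  if (is.null(extent)) {
    extent <- c(min(x), min(y), max(x), max(y))
  }
  x_edges <- seq(extent[1], extent[3] + bin_size, by = bin_size)
  y_edges <- seq(extent[2], extent[4] + bin_size, by = bin_size)
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  if (nx < 2 || ny < 1) {
    abort("trajectory covers too few bins", class = "gridscape_error_invalid_bin")
  }
  ix <- pmin(pmax(floor((x - extent[1]) / bin_size) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((y - extent[2]) / bin_size) + 1L, 1L), ny)
  idx <- (iy - 1L) * nx + ix
  occ <- tabulate(idx, nbins = nx * ny)
  sums <- rep(0, nx * ny)
  agg <- rowsum(response, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  grid <- matrix(ifelse(occ > 0, sums / pmax(occ, 1), NA_real_), nrow = nx)
  occ <- matrix(occ, nrow = nx)
  if (smoothing_sigma > 0) grid <- smooth_nadaraya(grid, smoothing_sigma)
  structure(
    list(grid = grid, occupancy = occ, x_edges = x_edges, y_edges = y_edges,
         bin_size = bin_size, extent = extent),
    class = "rate_map"
  )
}

# Gaussian smoothing with NA (unvisited) handling: normalised convolution
# restricted to visited bins; unvisited bins stay NA.  The Gaussian is
# separable, so the 2-D convolution runs as two 1-D passes.
conv1 <- function(m, k, along_rows) {
  rad <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  for (d in -rad:rad) {
    wk <- k[d + rad + 1]
    if (along_rows) {
      sr <- max(1, 1 - d):min(nr, nr - d)
      out[sr, ] <- out[sr, ] + wk * m[sr + d, , drop = FALSE]
    } else {
      sc <- max(1, 1 - d):min(nc, nc - d)
      out[, sc] <- out[, sc] + wk * m[, sc + d, drop = FALSE]
    }
  }
  out
}

smooth_nadaraya <- function(grid, sigma_bins) {
  rad <- max(1L, ceiling(3 * sigma_bins))
  k <- exp(-(-rad:rad)^2 / (2 * sigma_bins^2))
  vis <- !is.na(grid)
  z <- ifelse(vis, grid, 0)
  zsum <- conv1(conv1(z, k, TRUE), k, FALSE)
  wsum <- conv1(conv1(vis + 0, k, TRUE), k, FALSE)
  ifelse(vis & wsum > 0, zsum / wsum, NA_real_)
}

#' Firing-rate map
#'
#' Mean rectified response per spatial bin with Gaussian smoothing over
#' visited bins.
#'
#' @param traj Trajectory.
#' @param response Response vector aligned with `traj`.
#' @param bin_size Bin side in arena units.
#' @param smoothing_sigma Gaussian sigma in bins (0 disables smoothing).
#' @param rectify Clip negative responses to zero first (firing rates are
#'   non-negative).
#' @param extent Optional `c(xmin, ymin, xmax, ymax)`; defaults to the
#'   sampled range.
#' @return A `rate_map`: the `grid` matrix is indexed `[x bin, y bin]`
#'   with NA for unvisited bins.
#' @export
rate_map <- function(traj, response, bin_size = 0.01, smoothing_sigma = 1,
                     rectify = TRUE, extent = NULL) {
  if (length(response) != nrow(traj)) {
    abort("response and trajectory lengths differ", class = "gridscape_error_shape")
  }
  rate_map_xy(traj$x, traj$y, response, bin_size, smoothing_sigma, rectify, extent)
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d x %d bins of %.3g units, %.0f%% visited\n",
              nrow(x$grid), ncol(x$grid), x$bin_size,
              100 * mean(!is.na(x$grid))))
  invisible(x)
}


#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every 2-D lag, using
#' only pixels visited in both shifted copies (the per-lag sums are
#' computed exactly via FFTs).
#'
#' @param map A `rate_map`.
#' @param max_lag Maximum lag in arena units (default: half the smaller
#'   map extent).
#' @param min_overlap Minimum number of shared visited pixels for a lag
#'   to be retained.
#' @return An `autocorrelogram` with the correlation matrix `r`
#'   ((2L+1) x (2L+1), x lag along rows), the per-lag overlap count, and
#'   the bin size.
#' @export
autocorrelogram <- function(map, max_lag = NULL, min_overlap = 20) {
  G <- map$grid
  if (sum(!is.na(G)) < 2) {
    abort("rate map has fewer than 2 visited bins", class = "gridscape_error_degenerate_map")
  }
  if (is.null(max_lag)) {
    max_lag <- min(nrow(G), ncol(G)) * map$bin_size / 2
  }
  L <- max(1L, min(round(max_lag / map$bin_size), min(nrow(G), ncol(G)) - 1L))
  V <- ifelse(is.na(G), 0, 1)
  Z <- ifelse(is.na(G), 0, G)
  s <- cpp_ac_sums(Z, V, L)
  M <- round(s$M) # counts; remove FFT noise
  S12 <- s$S12; S1 <- s$S1; S2 <- s$S2; S11 <- s$S11; S22 <- s$S22
  num <- M * S12 - S1 * S2
  d1 <- M * S11 - S1^2
  d2 <- M * S22 - S2^2
  r <- num / sqrt(pmax(d1, 0) * pmax(d2, 0))
  r[!is.finite(r)] <- NA_real_
  r[M < min_overlap] <- NA_real_
  if (all(is.na(r))) {
    warning("degenerate (constant) rate map: undefined correlation at all lags")
  }
  structure(
    list(r = r, n_overlap = M, bin_size = map$bin_size, L = L,
         max_lag = L * map$bin_size),
    class = "autocorrelogram"
  )
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf("<autocorrelogram> lags to +/- %.3g units (%d bins)\n",
              x$max_lag, x$L))
  invisible(x)
}
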