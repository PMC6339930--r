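# Hexagonal gridness score (HGS), ellipticity and half-arena similarity.
#
# HGS = min[cor(r, r60), cor(r, r120)] - max[cor(r, r30), cor(r, r90),
# cor(r, r150)], where r is the autocorrelogram restricted to an annulus
# around the central ring of peaks and r_phi its rigid rotation by phi
# degrees.  A hexagonal lattice correlates highly with its 60/120 degree
# rotations but not with 30/90/150, giving scores up to 2; square
# lattices score negative (the 90-degree correlation is high).

# radially averaged profile of the autocorrelogram, by integer bin radius
radial_profile <- function(ac) {
  L <- ac$L
  off <- -L:L
  dist <- sqrt(outer(off^2, off^2, "+"))
  ring <- round(dist)
  vals <- tapply(as.vector(ac$r), as.vector(ring), mean, na.rm = TRUE)
  radii <- as.integer(names(vals))
  ord <- order(radii)
  list(radius = radii[ord], value = as.numeric(vals)[ord])
}

# Annulus mask bounds in bins: inner = first local minimum of the radial
# profile, outer = 2.5x the strongest ring-peak radius (capped at L);
# fallback [0.2, 0.8] L when no interior minimum exists.
annulus_bounds <- function(ac) {
  prof <- radial_profile(ac)
  v <- prof$value
  n <- length(v)
  inner <- NA_integer_
  for (i in 2:(n - 1)) {
    if (!is.na(v[i]) && !is.na(v[i - 1]) && !is.na(v[i + 1]) &&
        v[i] < v[i - 1] && v[i] <= v[i + 1]) {
      inner <- prof$radius[i]
      break
    }
  }
  if (is.na(inner) || inner >= 0.8 * ac$L) {
    return(list(inner = 0.2 * ac$L, outer = 0.8 * ac$L, peak_radius = NA_real_,
                confident = FALSE))
  }
  # the ring of six nearest peaks sits just beyond the first minimum;
  # restrict the peak search there so a distant noise maximum cannot
  # drag the annulus away from the ring
  beyond <- which(prof$radius > inner & prof$radius <= 3 * inner & !is.na(v))
  if (!length(beyond)) {
    return(list(inner = 0.2 * ac$L, outer = 0.8 * ac$L, peak_radius = NA_real_,
                confident = FALSE))
  }
  pk <- beyond[which.max(v[beyond])]
  peak_radius <- prof$radius[pk]
  # annulus hugs the first ring of peaks (the six nearest fields); going
  # wider mixes in the shared radial structure of outer rings, which
  # inflates every rotation correlation alike and washes the score out
  list(inner = inner, outer = min(1.5 * peak_radius, ac$L),
       peak_radius = peak_radius, confident = TRUE)
}

# Rotate a lag-centred matrix by `deg` degrees with bilinear
# interpolation; cells sampling outside or from NA neighbours become NA.
rotate_map <- function(r, deg) {
  L <- (nrow(r) - 1) / 2
  th <- deg * pi / 180
  off <- -L:L
  X <- matrix(off, nrow = 2 * L + 1, ncol = 2 * L + 1)
  Y <- t(X)
  # sample source coordinates (inverse rotation)
  xs <- cos(th) * X + sin(th) * Y
  ys <- -sin(th) * X + cos(th) * Y
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  get <- function(ix, iy) {
    ok <- ix >= -L & ix <= L & iy >= -L & iy <= L
    out <- matrix(NA_real_, nrow(r), ncol(r))
    out[ok] <- r[cbind(ix[ok] + L + 1, iy[ok] + L + 1)]
    out
  }
  v00 <- get(x0, y0); v10 <- get(x0 + 1, y0)
  v01 <- get(x0, y0 + 1); v11 <- get(x0 + 1, y0 + 1)
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Hexagonal gridness score
#'
#' Correlates the annulus-masked autocorrelogram with its rotations by
#' 30/60/90/120/150 degrees and combines them as
#' `min(cor60, cor120) - max(cor30, cor90, cor150)`.
#'
#' If no peak ring can be identified the score is computed on a default
#' annulus (0.2-0.8 of the maximum lag) and flagged via the
#' `"confident"` attribute.
#'
#' @param ac An `autocorrelogram`.
#' @return The score (in `[-2, 2]`), with attribute `confident`.
#' @export
hgs <- function(ac) {
  b <- annulus_bounds(ac)
  L <- ac$L
  off <- -L:L
  dist <- sqrt(outer(off^2, off^2, "+"))
  mask <- dist >= b$inner & dist <= b$outer
  base <- ac$r
  base[!mask] <- NA_real_
  if (sum(!is.na(base)) < 10 || stats::sd(base, na.rm = TRUE) == 0) {
    out <- NA_real_
    attr(out, "confident") <- FALSE
    return(out)
  }
  cors <- vapply(c(30, 60, 90, 120, 150), function(a) {
    rot <- rotate_map(ac$r, a)
    rot[!mask] <- NA_real_
    ok <- !is.na(base) & !is.na(rot)
    if (sum(ok) < 10) return(NA_real_)
    suppressWarnings(stats::cor(base[ok], rot[ok]))
  }, numeric(1))
  score <- min(cors[2], cors[4]) - max(cors[1], cors[3], cors[5])
  attr(score, "confident") <- b$confident
  score
}

# Local maxima of the autocorrelogram within the annulus, used for the
# ellipse fit: up to `k` strongest peaks with 8-neighbourhood dominance.
ring_peaks <- function(ac, k = 6) {
  b <- annulus_bounds(ac)
  L <- ac$L
  r <- ac$r
  n <- 2 * L + 1
  off <- -L:L
  dist <- sqrt(outer(off^2, off^2, "+"))
  # the ellipse describes the FIRST ring only; exclude second-shell peaks
  outer_lim <- if (!is.na(b$peak_radius)) {
    min(1.45 * b$peak_radius, b$outer)
  } else {
    b$outer
  }
  cand <- which(!is.na(r) & dist >= pmax(b$inner, 1) & dist <= outer_lim,
                arr.ind = TRUE)
  if (!nrow(cand)) return(NULL)
  is_peak <- apply(cand, 1, function(ij) {
    i <- ij[1]; j <- ij[2]
    v <- r[i, j]
    ni <- max(1, i - 1):min(n, i + 1)
    nj <- max(1, j - 1):min(n, j + 1)
    nb <- r[ni, nj]
    all(v >= nb, na.rm = TRUE)
  })
  cand <- cand[is_peak, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  vals <- r[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  pts <- cbind(cand[, 1] - L - 1, cand[, 2] - L - 1)
  # greedy selection with angular separation to avoid plateau duplicates
  sel <- integer(0)
  ang <- atan2(pts[, 2], pts[, 1])
  for (i in seq_len(nrow(pts))) {
    if (length(sel) >= k) break
    if (!length(sel)) { sel <- i; next }
    dphi <- abs(atan2(sin(ang[i] - ang[sel]), cos(ang[i] - ang[sel])))
    if (all(dphi > 20 * pi / 180)) sel <- c(sel, i)
  }
  pts[sel, , drop = FALSE] * ac$bin_size
}

#' Ellipticity of the central peak ring
#'
#' Least-squares fit of an origin-centred ellipse
#' `a x^2 + b x y + c y^2 = 1` to the ring peaks of the autocorrelogram;
#' returns the major/minor axis ratio (1 for an undistorted grid).
#'
#' @param ac An `autocorrelogram`.
#' @export
ellipticity <- function(ac) {
  pts <- ring_peaks(ac)
  if (is.null(pts) || nrow(pts) < 3) {
    abort("fewer than 3 ring peaks: ellipse undefined",
          class = "gridscape_error_undefined_ellipse")
  }
  A <- cbind(pts[, 1]^2, pts[, 1] * pts[, 2], pts[, 2]^2)
  coef <- tryCatch(solve(crossprod(A), crossprod(A, rep(1, nrow(pts)))),
                   error = function(e) NULL)
  if (is.null(coef)) {
    abort("degenerate peak configuration: ellipse undefined",
          class = "gridscape_error_undefined_ellipse")
  }
  Q <- matrix(c(coef[1], coef[2] / 2, coef[2] / 2, coef[3]), 2)
  ev <- eigen(Q, symmetric = TRUE)$values
  if (any(ev <= 0)) {
    abort("peaks do not bound an ellipse", class = "gridscape_error_undefined_ellipse")
  }
  sqrt(max(ev) / min(ev))
}

#' Similarity between the two halves of a rate map
#'
#' Splits the map by a vertical (or horizontal) cut, reflects one half
#' onto the other and returns the Pearson correlation over jointly
#' visited bins.
#'
#' @param map A `rate_map`.
#' @param axis `"vertical"` (cut at an x value) or `"horizontal"`.
#' @param split Cut coordinate in arena units; defaults to the middle of
#'   the extent.
#' @return Correlation, NA (with a warning) if either half is constant.
#' @export
half_map_similarity <- function(map, axis = c("vertical", "horizontal"),
                                split = NULL) {
  axis <- match.arg(axis)
  G <- if (axis == "vertical") map$grid else t(map$grid)
  edges <- if (axis == "vertical") map$x_edges else map$y_edges
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  if (is.null(split)) split <- (min(edges) + max(edges)) / 2
  li <- which(centers < split)
  ri <- which(centers > split)
  if (!length(li) || !length(ri)) {
    abort("empty half", class = "gridscape_error_insufficient_sampling")
  }
  k <- min(length(li), length(ri))
  left <- G[rev(li)[seq_len(k)], , drop = FALSE]   # nearest-to-cut first
  right <- G[ri[seq_len(k)], , drop = FALSE]
  ok <- !is.na(left) & !is.na(right)
  if (sum(ok) < 3) {
    abort("too few jointly visited bins", class = "gridscape_error_insufficient_sampling")
  }
  if (stats::sd(left[ok]) == 0 || stats::sd(right[ok]) == 0) {
    warning("constant half map: similarity undefined")
    return(NA_real_)
  }
  stats::cor(left[ok], right[ok])
}

#' Local and global gridness in a connected arena
#'
#' Global: HGS of the whole-arena rate map.  Local: mean of the HGS of
#' the two compartment maps (corridor samples excluded).
#'
#' @param env A connected arena.
#' @param traj Trajectory in that arena.
#' @param response Response vector aligned with `traj`.
#' @param bin_size,smoothing_sigma Rate-map parameters.
#' @param min_samples Minimum samples per compartment.
#' @return One-row tibble with `hgs_local` and `hgs_global`.
#' @export
local_global_hgs <- function(env, traj, response, bin_size = 0.01,
                             smoothing_sigma = 1, min_samples = 100) {
  if (!identical(env$kind, "connected")) {
    abort("arena is not a connected pair of rooms", class = "gridscape_error_invalid_shape")
  }
  comp <- arena_compartment(env, traj$x, traj$y)
  score_of <- function(keep) {
    if (sum(keep) < min_samples) {
      abort("compartment has too few samples",
            class = "gridscape_error_insufficient_sampling")
    }
    rm <- rate_map_xy(traj$x[keep], traj$y[keep], response[keep],
                      bin_size, smoothing_sigma)
    as.numeric(hgs(autocorrelogram(rm)))
  }
  global <- score_of(rep(TRUE, nrow(traj)))
  local_a <- score_of(comp == "a")
  local_b <- score_of(comp == "b")
  tibble(hgs_local = mean(c(local_a, local_b)), hgs_global = global)
}

#' Full gridness report for one neuron
#'
#' Bundles the whole-map HGS, ellipticity (NA if no ring can be fit),
#' and half-map similarity; for connected arenas also the local/global
#' scores.
#'
#' @inheritParams local_global_hgs
#' @param split Half-split coordinate (defaults to mid-extent).
#' @return One-row tibble.
#' @export
gridness_report <- function(env, traj, response, bin_size = 0.01,
                            smoothing_sigma = 1, split = NULL) {
  rm <- rate_map(traj, response, bin_size, smoothing_sigma)
  ac <- autocorrelogram(rm)
  ell <- tryCatch(ellipticity(ac), error = function(e) NA_real_)
  sim <- tryCatch(half_map_similarity(rm, split = split),
                  error = function(e) NA_real_)
  out <- tibble(hgs = as.numeric(hgs(ac)), ellipticity = ell,
                half_similarity = sim,
                hgs_local = NA_real_, hgs_global = NA_real_)
  if (identical(env$kind, "connected")) {
    lg <- local_global_hgs(env, traj, response, bin_size, smoothing_sigma)
    out$hgs_local <- lg$hgs_local
    out$hgs_global <- lg$hgs_global
  }
  out
}
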