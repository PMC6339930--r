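# ggplot2 views of arenas, trajectories, maps and study results.

#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_point geom_raster
#'   geom_tile coord_equal scale_fill_viridis_c labs theme_minimal
#'   geom_smooth facet_wrap
#' @export
ggplot2::autoplot

#' @export
autoplot.gridscape_arena <- function(object, ...) {
  ggplot(arena_boundary(object), aes(.data$x, .data$y, group = .data$ring)) +
    geom_path() +
    coord_equal() +
    labs(title = object$label, x = NULL, y = NULL) +
    theme_minimal()
}

#' @export
autoplot.gridscape_traj <- function(object, ...) {
  env <- attr(object, "arena")
  p <- ggplot(object, aes(.data$x, .data$y)) +
    geom_path(linewidth = 0.1, alpha = 0.6) +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
  if (!is.null(env)) {
    p <- p + geom_path(data = arena_boundary(env),
                       aes(group = .data$ring), colour = "red3")
  }
  p
}

#' @export
autoplot.rate_map <- function(object, ...) {
  xc <- (object$x_edges[-1] + object$x_edges[-length(object$x_edges)]) / 2
  yc <- (object$y_edges[-1] + object$y_edges[-length(object$y_edges)]) / 2
  d <- tidyr::expand_grid(x = xc, y = yc)
  d$rate <- as.vector(t(matrix(object$grid, nrow = nrow(object$grid))))
  d <- d[order(d$x, d$y), ]
  d$rate <- as.vector(object$grid[cbind(match(d$x, xc), match(d$y, yc))])
  ggplot(d, aes(.data$x, .data$y, fill = .data$rate)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "white") +
    coord_equal() +
    labs(fill = "rate") +
    theme_minimal()
}

#' @export
autoplot.autocorrelogram <- function(object, ...) {
  off <- (-object$L:object$L) * object$bin_size
  d <- tidyr::expand_grid(tx = off, ty = off)
  d$r <- as.vector(object$r[cbind(match(d$tx, off), match(d$ty, off))])
  ggplot(d, aes(.data$tx, .data$ty, fill = .data$r)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "white") +
    coord_equal() +
    labs(x = "x lag", y = "y lag", fill = "r") +
    theme_minimal()
}

#' Firing-field scatter over the trajectory
#'
#' @param traj Trajectory.
#' @param response Aligned response vector.
#' @param threshold_quantile Firing threshold quantile.
#' @export
plot_firing_field <- function(traj, response, threshold_quantile = 0.8) {
  ff <- firing_field_map(traj, response, threshold_quantile)
  autoplot(traj) +
    geom_point(data = ff, aes(.data$x, .data$y), colour = "red",
               size = 0.3)
}

#' @export
autoplot.gridscape_study <- function(object, ...) {
  sc <- object$scores
  xvar <- intersect(c("iter", "d", "r_inner", "n_sides"), names(sc))[1]
  yvars <- intersect(c("hgs", "hgs_local", "hgs_global"), names(sc))
  if (is.na(xvar) || !length(yvars)) {
    abort("study has no plottable trend columns", class = "gridscape_error_invalid_params")
  }
  long <- tidyr::pivot_longer(sc, dplyr::all_of(yvars),
                              names_to = "measure", values_to = "score")
  ggplot(long, aes(.data[[xvar]], .data$score)) +
    geom_point(alpha = 0.5) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    facet_wrap(~measure, scales = "free_y") +
    labs(title = object$study) +
    theme_minimal()
}
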