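# Ordinary least-squares trend fits used by every study: HGS (or
# accuracy) against training iteration, compartment distance, inner
# radius or polygon side count.  Across stochastic runs the studies
# report per-seed regressions, summarised by the majority slope sign and
# the median R^2.

#' Linear trend of y against x
#'
#' OLS fit with slope, R^2 and the two-sided p-value for slope != 0.
#'
#' @param x,y Numeric vectors (>= 3 points, `x` not constant).
#' @return A `trend_fit` with elements `slope`, `r_squared`, `p_value`,
#'   `slope_sign` and the underlying `lm` fit.
#' @export
trend_regression <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x)) {
    abort("need at least 3 paired points", class = "gridscape_error_degenerate_regression")
  }
  if (stats::sd(x) == 0) {
    abort("x is constant: regression undefined",
          class = "gridscape_error_degenerate_regression")
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  structure(
    list(slope = slope, r_squared = sm$r.squared, p_value = p,
         slope_sign = sign(slope), fit = fit, x = x, y = y),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope %.4g (%s), R^2 = %.3f, p = %.3g\n",
              x$slope, if (x$slope_sign >= 0) "increasing" else "decreasing",
              x$r_squared, x$p_value))
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = rownames(co), estimate = co[, 1], std_error = co[, 2],
    statistic = co[, 3], p_value = co[, 4]
  )
}

#' @export
glance.trend_fit <- function(x, ...) {
  tibble(slope = x$slope, slope_sign = x$slope_sign,
         r_squared = x$r_squared, p_value = x$p_value,
         n = length(x$x))
}

# Per-seed regressions of each y column against x_col; returns the
# per-seed fits plus a majority-sign / median-R^2 summary.
summarize_trends <- function(scores, x_col, y_cols) {
  if (length(unique(scores[[x_col]])) < 3) {
    abort("need at least 3 distinct x levels for a trend",
          class = "gridscape_error_degenerate_regression")
  }
  fits <- tidyr::expand_grid(seed = unique(scores$seed), measure = y_cols)
  fits <- purrr::pmap_dfr(fits, function(seed, measure) {
    d <- scores[scores$seed == seed, ]
    ok <- stats::complete.cases(d[[x_col]], d[[measure]])
    if (sum(ok) < 3) {
      return(tibble(seed = seed, measure = measure, slope = NA_real_,
                    slope_sign = NA_real_, r_squared = NA_real_,
                    p_value = NA_real_))
    }
    tr <- trend_regression(d[[x_col]][ok], d[[measure]][ok])
    tibble(seed = seed, measure = measure, slope = tr$slope,
           slope_sign = tr$slope_sign, r_squared = tr$r_squared,
           p_value = tr$p_value)
  })
  summary <- fits |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      majority_sign = sign(sum(sign(.data$slope), na.rm = TRUE)),
      frac_positive = mean(.data$slope > 0, na.rm = TRUE),
      median_r_squared = stats::median(.data$r_squared, na.rm = TRUE),
      n_seeds = sum(!is.na(.data$slope)),
      .groups = "drop"
    )
  list(trends = fits, summary = summary)
}

new_study <- function(study, scores, trends, summary, extra = list()) {
  structure(c(list(study = study, scores = scores, trends = trends,
                   summary = summary), extra),
            class = "gridscape_study")
}

#' @export
print.gridscape_study <- function(x, ...) {
  cat(sprintf("<study: %s>\n", x$study))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.gridscape_study <- function(x, ...) x$scores

#' @export
glance.gridscape_study <- function(x, ...) x$summary
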