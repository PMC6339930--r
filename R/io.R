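# Configuration, deterministic seeding and result serialisation.
#
# A run configuration is a nested list (model / experiment / decoder /
# analysis) read from YAML; unknown keys are rejected so typos fail
# loudly.  One master seed fans out into named per-stage seeds through a
# counter-based derivation, so adding a stage never perturbs the random
# streams of existing stages.

#' Derive named stage seeds from a master seed
#'
#' Counter-based: stage i gets
#' `(master * 48271 + i * 104729) mod (2^31 - 1)`, so streams are stable
#' under appending stages.
#'
#' @param master Integer master seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector.
#' @export
derive_seeds <- function(master, stages) {
  i <- seq_along(stages)
  s <- (as.numeric(master) * 48271 + i * 104729) %% 2147483647
  stats::setNames(as.integer(s) + 1L, stages)
}

#' Default run configuration
#'
#' Model defaults are the canonical parameter set: `omega_pi = 12*pi`
#' rad/s, `mu = 1`, `eta_f = eta_l = 0.01`, `beta = 50`, `dt = 0.01` s
#' and `n = 20` LAHN neurons.
#' @export
default_config <- function() {
  list(
    model = list(
      omega_pi = 12 * pi, mu = 1, beta = 50, dt = 0.01,
      eta_f = 0.01, eta_l = 0.01, n = 20,
      rho = 20, speed_cap = 0.5, min_speed = 0.05, grid_shape = c(8L, 8L),
      som_samples = 10000, som_epochs = 1,
      lahn_init_scale = 0.1, conv_tol = 1e-5, conv_window = 1000
    ),
    experiment = list(duration = 600, seeds = 1:5, n_checkpoints = 10),
    decoder = list(hidden_size = 20, learning_rate = 0.01, epochs = 200,
                   train_frac = 0.8),
    analysis = list(bin_size = 0.01, smoothing_sigma = 1, max_lag = 0.25,
                    threshold_quantile = 0.8)
  )
}

merge_validate <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- paste0(path, key)
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown configuration key: '%s'", full),
            class = "gridscape_error_config")
    }
    if (is.list(defaults[[key]]) && !is.list(user[[key]])) {
      abort(sprintf("configuration key '%s' must be a mapping", full),
            class = "gridscape_error_config")
    }
    defaults[[key]] <- if (is.list(defaults[[key]])) {
      merge_validate(defaults[[key]], user[[key]], paste0(full, "$"))
    } else {
      user[[key]]
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Missing keys take their defaults; unknown keys raise an error naming
#' the key.  An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("configuration file not found: %s", path),
          class = "gridscape_error_config")
  }
  # keep YAML-1.1 boolean-like scalars (n, y, yes, no, ...) as literal
  # strings: `n` is a configuration key (LAHN size), not a boolean
  keep <- function(x) x
  user <- tryCatch(
    yaml::read_yaml(path,
                    handlers = list("bool#yes" = keep, "bool#no" = keep)),
    error = function(e) {
    abort(sprintf("could not parse configuration: %s", conditionMessage(e)),
          class = "gridscape_error_config")
  })
  if (is.null(user)) user <- list()
  if (!is.list(user)) {
    abort("configuration must be a YAML mapping", class = "gridscape_error_config")
  }
  structure(merge_validate(default_config(), user), class = "run_config")
}

#' Model parameters from a configuration
#'
#' @param config A `run_config` (or the default configuration).
#' @export
config_model_params <- function(config = default_config()) {
  m <- config$model
  model_params(
    dt = m$dt, rho = m$rho, speed_cap = m$speed_cap, min_speed = m$min_speed,
    grid_shape = m$grid_shape, som_samples = m$som_samples,
    som_epochs = m$som_epochs, omega = m$omega_pi, mu = m$mu, beta = m$beta,
    n_lahn = m$n, eta_f = m$eta_f, eta_l = m$eta_l,
    lahn_init_scale = m$lahn_init_scale, conv_tol = m$conv_tol,
    conv_window = m$conv_window
  )
}

#' Write a trajectory to CSV
#'
#' Columns `t,x,y,theta,speed`; read back with [read_trajectory_csv()].
#' @param traj Trajectory.
#' @param path Output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "x", "y", "theta", "speed")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' @param path CSV with columns `t,x,y,theta,speed` (or at least
#'   `t,x,y`).
#' @param arena Optional arena to attach.
#' @export
read_trajectory_csv <- function(path, arena = NULL) {
  d <- utils::read.csv(path)
  need <- c("t", "x", "y")
  if (!all(need %in% names(d))) {
    abort("trajectory CSV needs columns t, x, y", class = "gridscape_error_config")
  }
  dt <- if (nrow(d) > 1) d$t[2] - d$t[1] else NA_real_
  if (!"theta" %in% names(d)) {
    d$theta <- c(0, atan2(diff(d$y), diff(d$x)))
  }
  if (!"speed" %in% names(d)) {
    d$speed <- c(0, sqrt(diff(d$x)^2 + diff(d$y)^2) / dt)
  }
  out <- as_tibble(d[, c("t", "x", "y", "theta", "speed")])
  structure(out, class = c("gridscape_traj", class(out)),
            arena = arena, dt = dt)
}

#' Export an arena boundary as CSV
#'
#' One row per vertex (`ring,x,y`), rings closed implicitly.
#' @param env Arena.
#' @param path Output file.
#' @export
write_arena_csv <- function(env, path) {
  b <- arena_boundary(env)
  utils::write.csv(as.data.frame(b), path, row.names = FALSE)
  invisible(path)
}

#' Save study results with a checksum manifest
#'
#' Writes the scores table as CSV and the summary as JSON, plus a
#' `manifest.json` listing each file with its MD5 checksum (identical
#' inputs give identical checksums).
#'
#' @param study A `gridscape_study`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a tibble.
#' @export
save_results <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory %s", out_dir),
          class = "gridscape_error_io")
  }
  files <- character(0)
  scores_path <- file.path(out_dir, "scores.csv")
  utils::write.csv(as.data.frame(study$scores), scores_path, row.names = FALSE)
  files <- c(files, scores_path)
  if (!is.null(study$trends)) {
    trends_path <- file.path(out_dir, "trends.csv")
    utils::write.csv(as.data.frame(study$trends), trends_path, row.names = FALSE)
    files <- c(files, trends_path)
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(study = study$study, summary = study$summary),
    summary_path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  files <- c(files, summary_path)
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = unname(file.size(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}
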