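# End-to-end model orchestration: trajectory -> head-direction sheet ->
# oscillator drive -> online LAHN training, with evenly spaced weight
# checkpoints and a convergence diagnostic on the afferent-weight drift.

#' Model parameter set
#'
#' Bundles every tunable of the three-stage model with its default.
#'
#' @param dt Timestep (s).
#' @param rho Turn-rate bound (rad/s) of the foraging model.
#' @param speed_cap Speed cap (units/s).
#' @param min_speed Speed floor (units/s).
#' @param grid_shape Head-direction sheet shape (the oscillator sheet is
#'   one-to-one with it).
#' @param som_samples,som_epochs Head-direction SOM training schedule.
#' @param omega,mu,beta Oscillator parameters, see [osc_params()].
#' @param n_lahn LAHN neuron count.
#' @param eta_f,eta_l LAHN learning rates.
#' @param lahn_init_scale Half-width of the initial LAHN weights.
#' @param conv_tol Convergence tolerance on the windowed afferent-weight
#'   drift (per element per step).
#' @param conv_window Drift window length (steps).
#' @export
model_params <- function(dt = 0.01, rho = 20, speed_cap = 0.5,
                         min_speed = 0.05,
                         grid_shape = c(8, 8), som_samples = 10000,
                         som_epochs = 1, omega = 12 * pi, mu = 1, beta = 50,
                         n_lahn = 20, eta_f = 0.01, eta_l = 0.01,
                         lahn_init_scale = 0.1, conv_tol = 1e-5,
                         conv_window = 1000) {
  as.list(environment())
}

#' Train the full grid-cell model in an arena
#'
#' Simulates a foraging session, trains the head-direction SOM, drives
#' the oscillator sheet along the trajectory and trains the LAHN online
#' on the oscillator states (both `u` and `v` components, so the input
#' dimension is twice the sheet size).  LAHN weights are snapshotted at
#' `n_checkpoints` evenly spaced iterations (plus the initial weights as
#' checkpoint 0).
#'
#' Randomness is fanned out from the master seed into independent
#' trajectory / SOM / LAHN streams, so runs are bit-reproducible and
#' adding a stage never perturbs the others.
#'
#' @param env Arena (static or transforming).
#' @param duration Session length (s).
#' @param params See [model_params()].
#' @param n_checkpoints Number of evenly spaced weight snapshots.
#' @param seed Master seed.
#' @param hd Optional pre-trained head-direction layer (reused across
#'   runs that share a SOM seed).
#' @return A `grid_model` object.
#' @export
train_grid_model <- function(env, duration = 600, params = model_params(),
                             n_checkpoints = 10, seed = 1, hd = NULL) {
  seeds <- derive_seeds(seed, c("trajectory", "som", "lahn"))
  traj <- simulate_trajectory(env, duration, dt = params$dt, rho = params$rho,
                              speed_cap = params$speed_cap,
                              min_speed = params$min_speed,
                              seed = seeds[["trajectory"]])
  if (is.null(hd)) {
    hd <- train_hd_som(params$grid_shape, params$som_samples,
                       params$som_epochs, seed = seeds[["som"]])
  }
  chi <- oscillator_drive(traj, hd, osc_params(params$omega, params$mu, params$beta))
  # Gain-normalise the LAHN drive by 1/sqrt(m): the oscillator population
  # norm is ~sqrt(N) whatever the sheet size, so this global gain makes
  # the response scale (and hence the stability of the printed learning
  # rates) independent of the sheet size without touching the principal
  # subspace or any spatial structure.
  chi <- chi / sqrt(ncol(chi))
  n_steps <- nrow(chi)
  net <- lahn_init(params$n_lahn, ncol(chi), params$eta_f, params$eta_l,
                   seed = seeds[["lahn"]], init_scale = params$lahn_init_scale)
  q0 <- net$q
  w0 <- net$w
  cp_iters <- unique(pmax(1L, round(seq_len(n_checkpoints) / n_checkpoints * n_steps)))
  fit <- lahn_train(net, chi, checkpoint_iters = cp_iters,
                    dq_window = params$conv_window)
  checkpoints <- c(list(list(iter = 0L, q = q0, w = w0)), fit$checkpoints)
  # converged once the windowed drift falls below tolerance after the
  # learning transient (the drift peak); early windows are quiet only
  # because responses start small
  peak <- if (length(fit$drift)) which.max(fit$drift) else 1L
  conv_idx <- which(fit$drift < params$conv_tol &
                      seq_along(fit$drift) > peak)
  convergence_iter <- if (length(conv_idx)) conv_idx[1] * params$conv_window else n_steps
  structure(
    list(
      arena = env, traj = traj, hd = hd, params = params, seed = seed,
      chi = chi, lahn = fit$net, response_log = fit$xi,
      checkpoints = checkpoints, drift = fit$drift,
      convergence_iter = convergence_iter, n_steps = n_steps
    ),
    class = "grid_model"
  )
}

#' Responses of a model checkpoint over the whole session
#'
#' Replays the stored oscillator stream through frozen LAHN weights.
#'
#' @param model A `grid_model`.
#' @param checkpoint `"final"` for the trained weights, or an index into
#'   `model$checkpoints` (1 is the initial weights, i.e. iteration 0).
#' @return T x n response matrix aligned with `model$traj`.
#' @export
replay_responses <- function(model, checkpoint = "final") {
  if (identical(checkpoint, "final")) {
    return(lahn_replay(model$chi, model$lahn$q, model$lahn$w))
  }
  cp <- model$checkpoints[[checkpoint]]
  lahn_replay(model$chi, cp$q, cp$w)
}

# Earliest stored checkpoint at or after 10% of the convergence
# iteration: the "partially learned" network of the decoder study.
partial_checkpoint_index <- function(model, fraction = 0.1) {
  iters <- vapply(model$checkpoints, `[[`, numeric(1), "iter")
  target <- fraction * model$convergence_iter
  idx <- which(iters >= target)
  if (length(idx)) idx[1] else length(iters)
}

#' @export
print.grid_model <- function(x, ...) {
  cat(sprintf(
    "<grid_model> arena: %s | %d steps | %d LAHN neurons | converged at step %d\n",
    x$arena$label, x$n_steps, x$lahn$n, x$convergence_iter
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-neuron gridness summary of a trained model
#'
#' Computes, for every LAHN neuron, the rate map of its final-weight
#' responses and the gridness statistics of the autocorrelogram.
#'
#' @param x A `grid_model`.
#' @param bin_size Rate-map bin size (arena units).
#' @param ... Unused.
#' @return A tibble with one row per neuron: `neuron`, `hgs`,
#'   `peak_rate`, `mean_rate`.
#' @export
tidy.grid_model <- function(x, bin_size = 0.01, ...) {
  resp <- replay_responses(x, "final")
  purrr::map_dfr(seq_len(ncol(resp)), function(i) {
    rm <- rate_map(x$traj, resp[, i], bin_size = bin_size)
    ac <- autocorrelogram(rm)
    tibble(
      neuron = i,
      hgs = hgs(ac),
      peak_rate = max(rm$grid, na.rm = TRUE),
      mean_rate = mean(rm$grid, na.rm = TRUE)
    )
  })
}

#' One-row summary of a trained model
#'
#' @inheritParams tidy.grid_model
#' @export
glance.grid_model <- function(x, ...) {
  tibble(
    arena = x$arena$label,
    n_steps = x$n_steps,
    n_neurons = x$lahn$n,
    convergence_iter = x$convergence_iter,
    final_drift = if (length(x$drift)) x$drift[length(x$drift)] else NA_real_
  )
}
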