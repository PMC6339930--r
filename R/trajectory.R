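# Curvature-constrained random foraging.
#
# The virtual animal is a point whose heading performs a bounded random
# walk (per-step turn <= rho * dt, with a fresh uniform draw on [-1, 1]
# each step) and whose speed equals the distance to the nearest wall,
# clamped between min_speed and speed_cap.  The border slowdown mimics
# thigmotactic deceleration; the floor keeps the slowdown from becoming
# an absorbing trap at the wall (pure distance-proportional speed makes
# log-distance a driftless random walk, stranding the agent at the
# boundary for most of the session).  Steps that would cross a wall are
# rejected and redrawn, then reflected off the wall normal.

#' Simulate a foraging trajectory
#'
#' @param env Arena (static or transforming).
#' @param duration Session length in seconds.
#' @param dt Timestep in seconds (default 0.01).
#' @param rho Maximum turn rate bound in rad/s; per-step turns are
#'   `runif(-1, 1) * rho * dt`.
#' @param speed_cap Maximum speed in units/s.
#' @param min_speed Speed floor in units/s (keeps the border slowdown
#'   from stranding the agent at the wall).
#' @param seed Optional integer seed (bit-reproducible given the seed).
#' @param start Optional length-2 start position; defaults to a uniformly
#'   sampled interior point.
#' @return A tibble of class `gridscape_traj` with columns `t`, `x`, `y`,
#'   `theta`, `speed`, carrying the arena and `dt` as attributes.
#' @export
simulate_trajectory <- function(env, duration, dt = 0.01, rho = 20,
                                speed_cap = 0.5, min_speed = 0.05,
                                seed = NULL, start = NULL) {
  if (duration <= 0 || dt <= 0 || rho <= 0 || speed_cap <= 0 || min_speed < 0) {
    abort("duration, dt, rho and speed_cap must be positive",
          class = "gridscape_error_invalid_params")
  }
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration / dt)
  transforming <- inherits(env, "gridscape_transforming")
  env0 <- arena_at(env, 0)

  if (is.null(start)) {
    start <- sample_interior_point(env0)
  } else if (!arena_contains(env0, start[1], start[2])) {
    abort("start point outside the arena", class = "gridscape_error_outside_arena")
  }
  if (wall_distance(env0, start[1], start[2]) <= dt * .Machine$double.eps^0.5) {
    abort("arena too small to take any step", class = "gridscape_error_degenerate_arena")
  }
  theta0 <- runif(1, 0, 2 * pi)

  raw <- if (transforming) {
    cpp_simulate_path_rect(env$length, env$breadth_start, env$breadth_end,
                           env$transform_time, n_steps, dt, rho, speed_cap,
                           min_speed, start[1], start[2], theta0)
  } else {
    cpp_simulate_path(env0$rings, n_steps, dt, rho, speed_cap, min_speed,
                      start[1], start[2], theta0)
  }
  out <- tibble(
    t = seq(0, by = dt, length.out = n_steps + 1L),
    x = raw$x, y = raw$y, theta = raw$theta, speed = raw$speed
  )
  structure(out,
            class = c("gridscape_traj", class(out)),
            arena = env, dt = dt)
}

sample_interior_point <- function(env0, max_tries = 10000) {
  bb <- env0$bbox
  for (i in seq_len(max_tries)) {
    p <- c(runif(1, bb["xmin"], bb["xmax"]), runif(1, bb["ymin"], bb["ymax"]))
    if (arena_contains(env0, p[1], p[2]) &&
        cpp_wall_distance(env0$rings, p[1], p[2]) > 1e-6) {
      return(unname(p))
    }
  }
  abort("could not find an interior start point",
        class = "gridscape_error_degenerate_arena")
}

#' Per-step speed from positions
#'
#' Finite-difference speeds `||X(t) - X(t-1)|| / dt`; the first sample is 0.
#' This is the speed signal fed to the oscillator layer.
#' @param traj A trajectory.
#' @export
speed_series <- function(traj) {
  if (nrow(traj) < 2) {
    abort("need at least 2 samples", class = "gridscape_error_invalid_params")
  }
  dt <- attr(traj, "dt")
  c(0, sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt)
}

#' @export
print.gridscape_traj <- function(x, ...) {
  env <- attr(x, "arena")
  cat(sprintf("<trajectory> %d samples, dt = %g s, arena: %s\n",
              nrow(x), attr(x, "dt"), env$label))
  NextMethod()
}
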