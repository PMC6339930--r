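# Oscillatory path-integration layer.
#
# One forced limit-cycle (Hopf normal form) oscillator per head-direction
# neuron:
#   du/dt = -v [Omega + beta s thetaHD] + u [mu - (u^2 + v^2)]
#   dv/dt =  u [Omega + beta s thetaHD] + v [mu - (u^2 + v^2)]
# With s the running speed, the phase in excess of the carrier Omega*t
# integrates beta * (displacement projected on the preferred direction):
# each oscillator path-integrates one directional component of position.
# Because the frequency is constant within a timestep, the system is
# advanced exactly in polar coordinates (rigid phase rotation plus the
# closed-form logistic radius relaxation).  Exact phase matters: any
# per-step phase truncation error accumulates differently across
# oscillators and slowly translates the interference lattice over a
# session, washing spatial structure out of the rate maps (explicit
# Euler additionally inflates the limit-cycle radius several-fold at
# these frequencies).

#' Oscillator layer parameters
#'
#' @param omega Carrier angular frequency, rad/s (default `12*pi`).
#' @param mu Limit-cycle parameter; the unforced radius is `sqrt(mu)`.
#' @param beta Spatial scale: phase advances by `beta` radians per unit
#'   distance travelled along a neuron's preferred direction, so the
#'   intrinsic spatial wavelength is `2*pi/beta` arena units.
#' @export
osc_params <- function(omega = 12 * pi, mu = 1, beta = 50) {
  list(omega = omega, mu = mu, beta = beta)
}

#' One integration step of the oscillator sheet
#'
#' Advances every oscillator by one timestep with instantaneous angular
#' frequency `omega + beta * s * hd_act`, using the exact polar-form
#' update (rigid phase rotation, closed-form radius relaxation).
#'
#' @param state List with numeric vectors `u` and `v`.
#' @param hd_act Head-direction sheet activation (same length as `u`).
#' @param s Running speed (units/s).
#' @param dt Timestep (s).
#' @param params See [osc_params()].
#' @return Updated state list.
#' @export
step_oscillators <- function(state, hd_act, s, dt, params = osc_params()) {
  u <- state$u; v <- state$v
  if (length(u) != length(hd_act)) {
    abort("hd_act length must match oscillator count",
          class = "gridscape_error_shape")
  }
  om <- params$omega + params$beta * s * hd_act
  mu <- params$mu
  r2 <- u^2 + v^2
  phi <- atan2(v, u) + om * dt
  g <- exp(2 * mu * dt)
  r2n <- if (mu != 0) mu * r2 * g / (mu + r2 * (g - 1)) else r2 / (1 + 2 * r2 * dt)
  r <- sqrt(r2n)
  u2 <- r * cos(phi)
  v2 <- r * sin(phi)
  if (any(!is.finite(u2)) || any(!is.finite(v2))) {
    abort("oscillator state diverged", class = "gridscape_error_numeric_overflow")
  }
  list(u = u2, v = v2)
}

#' Drive the oscillator sheet along a trajectory
#'
#' Integrates the whole sheet over a trajectory, with the per-step speed
#' taken from position differences and the head-direction activation from
#' the heading.  All oscillators start on the limit cycle at phase 0.
#'
#' @param traj A trajectory from [simulate_trajectory()].
#' @param hd A trained head-direction layer.
#' @param params See [osc_params()].
#' @return A T x 2N matrix of oscillator states, columns `u_1..u_N,
#'   v_1..v_N`, rows aligned with the trajectory samples.
#' @export
oscillator_drive <- function(traj, hd, params = osc_params()) {
  dt <- attr(traj, "dt")
  n <- ncol(hd$W)
  cpp_osc_drive(cbind(traj$x, traj$y), traj$theta, hd$W,
                params$omega, params$beta, params$mu, dt,
                rep(sqrt(params$mu), n), rep(0, n))
}
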