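# Lateral anti-Hebbian network (LAHN): a single layer of n neurons with
# Hebbian afferent weights q (with an Oja-style decay that bounds their
# norm) and anti-Hebbian lateral weights w (zero diagonal).  The
# elementary response recurrence is
#   xi_i(t) = sum_j q_ij chi_j(t) + sum_k w_ik xi_k(t-1)
# The lateral loop is much faster than the 10 ms input timestep, so
# during training and replay the recurrence is taken as settled within
# each sample: xi(t) = (I - w)^{-1} q chi(t).  (The settled solution is
# also the only bounded reading once anti-Hebbian learning grows |w|
# beyond unit spectral radius; the raw one-step recurrence diverges.)
# Plasticity:
#   dq_ij =  eta_F [chi_j(t) xi_i(t) - q_ij xi_i(t)^2]
#   dw_ik = -eta_L  xi_i(t) xi_k(t-1)
# Trained this way the rows of q converge to the principal subspace of
# the input stream while the lateral weights decorrelate the responses.

#' Initialise a LAHN
#'
#' @param n Number of neurons (default 20).
#' @param m Input dimension.
#' @param eta_f,eta_l Afferent and lateral learning rates.
#' @param seed Optional seed for the uniform(-init_scale, init_scale)
#'   weight initialisation.
#' @param init_scale Half-width of the initial weight distribution.
#' @return An object of class `lahn`.
#' @export
lahn_init <- function(n = 20, m, eta_f = 0.01, eta_l = 0.01, seed = NULL,
                      init_scale = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  m <- as.integer(m)
  q <- matrix(runif(n * m, -init_scale, init_scale), nrow = n)
  w <- matrix(runif(n * n, -init_scale, init_scale), nrow = n)
  diag(w) <- 0
  structure(list(q = q, w = w, n = n, m = m, eta_f = eta_f, eta_l = eta_l),
            class = "lahn")
}

#' Elementary LAHN response recurrence
#'
#' One unrolled step of the lateral recurrence, with the previous
#' response in the lateral term.  Training and replay use the settled
#' form of this recurrence ([lahn_settled_response()]).
#'
#' @param net A `lahn`.
#' @param chi Input vector of length `m`.
#' @param xi_prev Previous response (defaults to zeros).
#' @export
lahn_response <- function(net, chi, xi_prev = rep(0, net$n)) {
  if (length(chi) != net$m || length(xi_prev) != net$n) {
    abort("input dimensions do not match the network",
          class = "gridscape_error_shape")
  }
  drop(net$q %*% chi + net$w %*% xi_prev)
}

#' Settled LAHN response to one input sample
#'
#' The fixed point of the lateral recurrence within one sample:
#' `solve(I - w, q %*% chi)`.  Equals `q %*% chi` when `w = 0`.
#'
#' @inheritParams lahn_response
#' @export
lahn_settled_response <- function(net, chi) {
  if (length(chi) != net$m) {
    abort("input dimensions do not match the network",
          class = "gridscape_error_shape")
  }
  drop(solve(diag(net$n) - net$w, net$q %*% chi))
}

#' One LAHN plasticity step
#'
#' Applies the Hebbian/anti-Hebbian updates and re-zeroes the lateral
#' diagonal.
#'
#' @inheritParams lahn_response
#' @param xi Current response.
#' @export
lahn_update <- function(net, chi, xi, xi_prev) {
  if (length(chi) != net$m || length(xi) != net$n || length(xi_prev) != net$n) {
    abort("input dimensions do not match the network",
          class = "gridscape_error_shape")
  }
  net$q <- net$q + net$eta_f * (outer(xi, chi) - net$q * xi^2)
  net$w <- net$w - net$eta_l * outer(xi, xi_prev)
  diag(net$w) <- 0
  net
}

#' Train a LAHN on an input stream
#'
#' Runs the online response/update loop over every row of `chi`,
#' optionally snapshotting the weights at given iterations, and returns
#' the per-step responses together with a drift diagnostic (mean absolute
#' net change of `q` per element per step over windows of `dq_window`
#' steps).
#'
#' @param net A `lahn`.
#' @param chi T x m input matrix.
#' @param checkpoint_iters Integer iterations (1-based) at which to save
#'   weight snapshots.
#' @param dq_window Window length for the drift diagnostic.
#' @return List with the trained `net`, responses `xi` (T x n), a list of
#'   `checkpoints` (iter, q, w) and the `drift` vector.
#' @export
lahn_train <- function(net, chi, checkpoint_iters = integer(0),
                       dq_window = 500) {
  if (ncol(chi) != net$m) {
    abort("input dimensions do not match the network",
          class = "gridscape_error_shape")
  }
  res <- cpp_lahn_train(chi, net$q, net$w, net$eta_f, net$eta_l,
                        as.integer(sort(unique(checkpoint_iters))), dq_window)
  net$q <- res$q
  net$w <- res$w
  cps <- purrr::pmap(
    list(sort(unique(checkpoint_iters)), res$q_checkpoints, res$w_checkpoints),
    function(iter, q, w) list(iter = iter, q = q, w = w)
  )
  list(net = net, xi = res$xi, checkpoints = cps, drift = res$dq_drift)
}

#' Replay an input stream through frozen LAHN weights
#'
#' Forward pass only (no plasticity); used to evaluate checkpoint weights
#' over a whole session.
#'
#' @param chi T x m input matrix.
#' @param q,w Weight matrices.
#' @export
lahn_replay <- function(chi, q, w) {
  cpp_lahn_replay(chi, q, w)
}

#' @export
print.lahn <- function(x, ...) {
  cat(sprintf("<lahn> %d neurons, input dim %d, eta_F=%g eta_L=%g\n",
              x$n, x$m, x$eta_f, x$eta_l))
  invisible(x)
}
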