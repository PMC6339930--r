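# Head-direction layer: a Kohonen self-organizing map over unit heading
# vectors psi = [cos(theta), sin(theta)].  After training, each neuron's
# (unit-norm) weight vector is its preferred direction and the sheet
# response to a heading is the dot product psi' W, i.e. the cosine of the
# angle between heading and preferred direction.

#' Train the head-direction SOM
#'
#' Standard Kohonen fit on unit vectors with headings drawn uniformly on
#' `[0, 2*pi)`.  The neighbourhood is a Gaussian on the 2-D sheet whose
#' radius shrinks from half the sheet to below one neuron; the learning
#' rate decays from 0.5 to 0.01.  Weight vectors are renormalised to unit
#' length after every update.
#'
#' @param grid_shape Integer pair, sheet rows x columns.
#' @param n_samples Training samples per epoch.
#' @param epochs Number of passes.
#' @param seed Optional seed.
#' @return An object of class `hd_layer` with the 2 x N weight matrix
#'   `W`, the sheet shape and each neuron's preferred direction.
#' @export
train_hd_som <- function(grid_shape = c(8, 8), n_samples = 10000, epochs = 1,
                         seed = NULL) {
  if (epochs <= 0) {
    abort("epochs must be positive", class = "gridscape_error_invalid_training")
  }
  if (prod(grid_shape) < 4) {
    abort("need at least 4 neurons", class = "gridscape_error_invalid_training")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- prod(grid_shape)
  # sheet coordinates of each neuron (row-major)
  rc <- cbind(
    rep(seq_len(grid_shape[1]), times = grid_shape[2]),
    rep(seq_len(grid_shape[2]), each = grid_shape[1])
  )
  W <- matrix(rnorm(2 * n), nrow = 2)
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")

  total <- n_samples * epochs
  sigma0 <- max(grid_shape) / 2
  sigma1 <- 0.5
  lr0 <- 0.5
  lr1 <- 0.01
  thetas <- runif(total, 0, 2 * pi)
  for (it in seq_len(total)) {
    frac <- (it - 1) / max(total - 1, 1)
    sigma <- sigma0 * (sigma1 / sigma0)^frac
    lr <- lr0 * (lr1 / lr0)^frac
    psi <- c(cos(thetas[it]), sin(thetas[it]))
    act <- psi %*% W
    win <- which.max(act)
    d2 <- (rc[, 1] - rc[win, 1])^2 + (rc[, 2] - rc[win, 2])^2
    h <- exp(-d2 / (2 * sigma^2))
    W <- W + lr * (psi - W) * rep(h, each = 2)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  }
  structure(
    list(W = W, grid_shape = as.integer(grid_shape),
         preferred = atan2(W[2, ], W[1, ]) %% (2 * pi), trained = TRUE),
    class = "hd_layer"
  )
}

#' Head-direction sheet response
#'
#' Dot product of the heading unit vector with every neuron's weight
#' vector: `cos(heading - preferred)` for unit-norm weights.
#'
#' @param hd A trained `hd_layer`.
#' @param heading Heading(s) in radians.
#' @return Numeric vector (one heading) or T x N matrix (several).
#' @export
hd_response <- function(hd, heading) {
  stopifnot(inherits(hd, "hd_layer"))
  psi <- rbind(cos(heading), sin(heading))
  out <- t(psi) %*% hd$W
  if (length(heading) == 1L) drop(out) else out
}

#' @export
print.hd_layer <- function(x, ...) {
  cat(sprintf("<hd_layer> %d x %d sheet, preferred directions cover [0, 2pi)\n",
              x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}
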