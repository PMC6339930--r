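# MLP decoder: a single-hidden-layer perceptron with sigmoid units,
# trained by plain online backpropagation on squared error, used to read
# the arena configuration (rectangle vs square) out of LAHN population
# responses.  Accuracy is always reported on a stratified held-out
# split; mean squared output error is reported per configuration.

#' Train the configuration decoder
#'
#' @param x Numeric matrix (samples x features) of LAHN responses.
#' @param labels Configuration label per sample; any two-level vector
#'   (e.g. 1/2).  The second level maps to target output 1.
#' @param hidden_size Hidden units.
#' @param learning_rate Backpropagation step size.
#' @param epochs Training epochs (one pass over the training split each).
#' @param train_frac Fraction of samples used for training; the rest is
#'   the held-out evaluation set (split stratified by label).
#' @param threshold Output threshold for classification.
#' @param init_scale Half-width of the uniform weight initialisation.
#' @param seed Optional seed (initialisation, shuffling and split).
#' @return An `mlp_decoder` with held-out `accuracy`, `mse_by_config`,
#'   a `predictions` tibble and the fitted weights.
#' @export
train_decoder <- function(x, labels, hidden_size = 20, learning_rate = 0.01,
                          epochs = 200, train_frac = 0.8, threshold = 0.5,
                          init_scale = 0.1, seed = NULL) {
  x <- as.matrix(x)
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    abort("labels must contain exactly two classes",
          class = "gridscape_error_degenerate_labels")
  }
  if (length(labels) != nrow(x)) {
    abort("labels and x lengths differ", class = "gridscape_error_shape")
  }
  if (!is.null(seed)) set.seed(seed)
  # one global gain so the fixed learning rate / weight scale are
  # meaningful whatever the physical scale of the responses; relative
  # structure across features (what distinguishes a trained from a
  # partially trained LAHN) is untouched
  gain <- 1 / stats::sd(x)
  if (!is.finite(gain)) gain <- 1
  x <- x * gain
  y <- as.numeric(labels == lev[2])
  # stratified split
  test_idx <- unlist(lapply(lev, function(l) {
    i <- which(labels == l)
    sample(i, max(1, round((1 - train_frac) * length(i))))
  }))
  train_idx <- setdiff(seq_len(nrow(x)), test_idx)
  fit <- cpp_mlp_train(x[train_idx, , drop = FALSE], y[train_idx],
                       hidden_size, learning_rate, epochs, init_scale)
  out_test <- as.numeric(cpp_mlp_predict(x[test_idx, , drop = FALSE],
                                         fit$W1, fit$b1, fit$W2, fit$b2))
  pred <- as.integer(out_test > threshold)
  acc <- mean(pred == y[test_idx])
  err2 <- (out_test - y[test_idx])^2
  mse_by_config <- tibble(config = lev,
                          mse = c(mean(err2[y[test_idx] == 0]),
                                  mean(err2[y[test_idx] == 1])))
  structure(
    list(
      weights = fit[c("W1", "b1", "W2", "b2")], gain = gain,
      levels = lev, threshold = threshold, accuracy = acc,
      mse_by_config = mse_by_config,
      mse_curve = fit$mse_curve,
      predictions = tibble(index = test_idx, label = labels[test_idx],
                           output = out_test,
                           predicted = lev[pred + 1L]),
      hidden_size = hidden_size, learning_rate = learning_rate,
      epochs = epochs
    ),
    class = "mlp_decoder"
  )
}

#' @export
print.mlp_decoder <- function(x, ...) {
  cat(sprintf("<mlp_decoder> %d hidden units | held-out accuracy %.2f%%\n",
              x$hidden_size, 100 * x$accuracy))
  invisible(x)
}

#' Decoder outputs for new samples
#'
#' @param object An `mlp_decoder`.
#' @param newdata Matrix of samples.
#' @param type `"response"` for the sigmoid output in `[0, 1]`,
#'   `"class"` for thresholded labels.
#' @param ... Unused.
#' @export
predict.mlp_decoder <- function(object, newdata, type = c("response", "class"),
                                ...) {
  type <- match.arg(type)
  out <- as.numeric(cpp_mlp_predict(as.matrix(newdata) * object$gain, object$weights$W1,
                                    object$weights$b1, object$weights$W2,
                                    object$weights$b2))
  if (type == "response") out else object$levels[(out > object$threshold) + 1L]
}

#' @export
glance.mlp_decoder <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         mse_config_1 = x$mse_by_config$mse[1],
         mse_config_2 = x$mse_by_config$mse[2],
         hidden_size = x$hidden_size, epochs = x$epochs)
}
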