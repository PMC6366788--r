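# Grid-search estimator of working-memory capacity from a recall curve.

#' Fit working-memory capacity to an observed recall curve
#'
#' Estimates the buffer capacity C that best explains a per-test-trial
#' series of correctly recalled items, by grid search: for each candidate
#' C the chunk-buffer model predicts a cumulative recall curve over the
#' same number of trials, and the candidate minimising the sum of squared
#' deviations from the observed series wins. Ties are broken toward the
#' smallest candidate, so the reported C is the smallest capacity
#' consistent with the data (capacities within one chunk-size equivalence
#' class predict identical curves and are not distinguishable from recall
#' alone). Predictions use the literal storage condition (no forced
#' progress), so candidates below the single-element load predict zero
#' recall and are rejected by data that show any learning.
#'
#' @param CR Numeric vector: observed CR per test trial, in trial order.
#' @param loads Per-element informational loads: either a single value
#'   (uniform) or a vector of length `n`.
#' @param n Sequence length (items); defaults to `max` of loads length or
#'   `max(CR)`.
#' @param C_grid Candidate capacities, default `seq(0.5, 8, by = 0.5)`.
#' @return An object of class `capacity_fit`.
#' @examples
#' obs <- simulate_learning(rep(1, 16), buffer_config(4), 10)$cumulative_recall
#' fit <- fit_capacity(obs, loads = 1, n = 16)
#' coef(fit)  # C = 4
#' @export
fit_capacity <- function(CR, loads, n = NULL,
                         C_grid = seq(0.5, 8, by = 0.5)) {
  if (length(CR) < 1) stop_domain("need at least one observed trial")
  if (is.null(n)) n <- max(length(loads), max(CR, 1))
  if (length(loads) == 1L) loads <- rep(loads, n)
  if (length(loads) != n) stop_domain("loads must have length 1 or n")
  n_trials <- length(CR)
  pred_curve <- function(C) {
    tr <- simulate_learning(element_sequence(loads),
                            buffer_config(C, force_progress = FALSE),
                            max_iters = n_trials)
    rec <- tr$cumulative_recall
    if (length(rec) < n_trials)
      rec <- c(rec, rep(utils::tail(rec, 1), n_trials - length(rec)))
    rec[seq_len(n_trials)]
  }
  preds <- vapply(C_grid, pred_curve, numeric(n_trials))
  preds <- matrix(preds, nrow = n_trials)
  sse <- colSums((preds - CR)^2)
  best <- which(sse == min(sse))[1] # smallest candidate on ties
  structure(list(
    C = C_grid[best], C_grid = C_grid, sse = sse,
    observed = CR, fitted = preds[, best], loads = loads, n = n,
    sigma = sqrt(min(sse) / n_trials)
  ), class = "capacity_fit")
}

#' @export
print.capacity_fit <- function(x, ...) {
  cat(sprintf("Working-memory capacity fit: C = %g (grid %g..%g, SSE = %.4g)\n",
              x$C, min(x$C_grid), max(x$C_grid), min(x$sse)))
  invisible(x)
}

#' @export
summary.capacity_fit <- function(object, ...) {
  cat(sprintf("Capacity fit over %d trials, sequence length %d\n",
              length(object$observed), object$n))
  cat(sprintf("  C-hat = %g   residual SD = %.3f items\n",
              object$C, object$sigma))
  ties <- object$C_grid[object$sse == min(object$sse)]
  if (length(ties) > 1)
    cat("  equivalent capacities (identical predicted curve):",
        paste(ties, collapse = ", "), "\n")
  cat("  observed:", paste(object$observed, collapse = " "), "\n")
  cat("  fitted:  ", paste(object$fitted, collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.capacity_fit <- function(object, ...) c(C = object$C)

#' @export
fitted.capacity_fit <- function(object, ...) object$fitted

#' @export
residuals.capacity_fit <- function(object, ...) object$observed - object$fitted

#' Predict the recall curve from a fitted capacity
#'
#' @param object A `capacity_fit`.
#' @param iterations Number of learning iterations to predict; defaults to
#'   the observed series length.
#' @param ... Unused.
#' @return Numeric vector of predicted cumulative recall.
#' @export
predict.capacity_fit <- function(object, iterations = NULL, ...) {
  if (is.null(iterations)) iterations <- length(object$observed)
  tr <- simulate_learning(element_sequence(object$loads),
                          buffer_config(object$C, force_progress = FALSE),
                          max_iters = iterations)
  rec <- tr$cumulative_recall
  if (length(rec) < iterations)
    rec <- c(rec, rep(utils::tail(rec, 1), iterations - length(rec)))
  rec[seq_len(iterations)]
}

#' Simulate recall series from a fitted capacity
#'
#' Draws `nsim` noisy recall series around the fitted model's predicted
#' curve, using the residual SD as the trial-level noise scale.
#'
#' @param object A `capacity_fit`.
#' @param nsim Number of series.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return data.frame with one column per simulated series.
#' @export
simulate.capacity_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    mu <- object$fitted
    out <- replicate(nsim, pmin(object$n, pmax(0, round(
      mu + stats::rnorm(length(mu), 0, object$sigma)))))
    as.data.frame(matrix(out, nrow = length(mu)))
  })
}

#' Plot a capacity fit
#'
#' Observed CR and fitted cumulative-recall curve against test trial.
#'
#' @param x A `capacity_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.capacity_fit <- function(x, ...) {
  trials <- seq_along(x$observed)
  graphics::plot(trials, x$observed, pch = 19,
                 xlab = "Test trial", ylab = "CR (items)",
                 ylim = c(0, x$n), ...)
  graphics::lines(trials, x$fitted, type = "b", pch = 1, lty = 2)
  graphics::legend("bottomright", legend = c("observed", "fitted"),
                   pch = c(19, 1), lty = c(NA, 2), bty = "n")
  invisible(x)
}
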