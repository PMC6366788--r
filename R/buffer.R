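# Limited-capacity working-memory buffer and iterative chunk learning.
#
# A buffer of capacity C (buffer units) stores sequence elements in serial
# order only while residual capacity Q = C - sum(e_i) stays non-negative.
# Each learning iteration fills the buffer from the current frontier of the
# unlearned sequence, writes the stored run to long-term memory as one
# chunk, and repeats until the whole sequence is learned. Smaller C or
# larger element loads shrink the chunks and slow learning.

#' Working-memory buffer configuration
#'
#' @param C Storage capacity in buffer units; must be > 0 (may be `Inf`).
#' @param force_progress If `TRUE` (default) an element whose load alone
#'   exceeds `C` is still learned one-per-iteration, so simulations always
#'   terminate; `FALSE` reproduces the literal storage condition, under
#'   which such an element is never stored.
#' @return An object of class `buffer_config`.
#' @export
buffer_config <- function(C, force_progress = TRUE) {
  check_num1(C, "C")
  if (C <= 0) stop_domain("C must be > 0")
  structure(list(C = C, force_progress = isTRUE(force_progress)),
            class = "buffer_config")
}

#' Residual buffer capacity
#'
#' `Q = C - sum(loads_held)`. A negative value signals that the storage
#' condition `Q >= 0` is violated and the held set does not fit.
#'
#' @param cfg A [buffer_config()].
#' @param loads_held Numeric vector of loads currently held (may be empty).
#' @return Residual capacity in buffer units (possibly negative).
#' @export
residual_capacity <- function(cfg, loads_held = numeric()) {
  if (!inherits(cfg, "buffer_config")) cfg <- buffer_config(cfg)
  cfg$C - sum(loads_held)
}

#' An element sequence of informational loads
#'
#' @param loads Numeric vector of per-element loads, all > 0.
#' @return An object of class `element_sequence`.
#' @export
element_sequence <- function(loads) {
  if (!is.numeric(loads) || any(!is.finite(loads)) || any(loads <= 0))
    stop_domain("all element loads must be finite and > 0")
  structure(list(loads = as.numeric(loads), n = length(loads)),
            class = "element_sequence")
}

#' Largest chunk storable from a given frontier
#'
#' The largest run of consecutive elements starting at `start` whose loads
#' sum to at most `C`. With `force_progress` on, a run of zero (first
#' element alone exceeds capacity) is promoted to one so learning advances.
#'
#' @param seq An [element_sequence()] (or bare numeric load vector).
#' @param start 1-based index of the first unlearned element; must lie in
#'   `1..n+1` (`n+1` means the sequence is complete and the chunk is 0).
#' @param cfg A [buffer_config()].
#' @return Chunk size in items.
#' @export
max_chunk <- function(seq, start, cfg) {
  if (!inherits(seq, "element_sequence")) seq <- element_sequence(seq)
  if (!inherits(cfg, "buffer_config")) cfg <- buffer_config(cfg)
  n <- seq$n
  if (start < 1 || start > n + 1) stop_domain("start out of range")
  if (start == n + 1) return(0L)
  csum <- cumsum(seq$loads[start:n])
  m <- sum(csum <= cfg$C)
  if (m == 0L && cfg$force_progress) m <- 1L
  as.integer(m)
}

#' Simulate iterative chunk learning of a sequence
#'
#' Repeatedly stores the largest storable chunk at the current frontier,
#' writes it to long-term memory, and advances, until the sequence is
#' complete or `max_iters` iterations have run.
#'
#' @inheritParams max_chunk
#' @param max_iters Maximum number of iterations (>= 1), default 100.
#' @param decay Fraction of the learned store lost between iterations, in
#'   `[0, 1)`. Default 0: the learning process itself has no forgetting;
#'   the hook exists for exploring forgetful variants, under which the
#'   recall curve need not be monotone and completion may never occur.
#' @return A `learning_trace`: list with `chunk_sizes` (items per
#'   iteration), `cumulative_recall` (frontier after each iteration),
#'   `iterations_to_complete` (integer, or `NA` if `max_iters` was hit
#'   first), `n` and `C`.
#' @examples
#' tr <- simulate_learning(element_sequence(rep(1, 30)), buffer_config(4))
#' tr$iterations_to_complete  # 8
#' @export
simulate_learning <- function(seq, cfg, max_iters = 100, decay = 0) {
  if (!inherits(seq, "element_sequence")) seq <- element_sequence(seq)
  if (!inherits(cfg, "buffer_config")) cfg <- buffer_config(cfg)
  if (max_iters < 1) stop_domain("max_iters must be >= 1")
  if (decay < 0 || decay >= 1) stop_domain("decay must be in [0, 1)")
  n <- seq$n
  frontier <- 0L
  chunks <- integer(0)
  recall <- integer(0)
  it <- 0L
  while (frontier < n && it < max_iters) {
    it <- it + 1L
    if (decay > 0 && it > 1L)
      frontier <- as.integer(floor(frontier * (1 - decay)))
    m <- max_chunk(seq, frontier + 1L, cfg)
    if (m == 0L) { # literal condition, no progress possible: stall
      chunks <- c(chunks, 0L)
      recall <- c(recall, frontier)
      next
    }
    frontier <- frontier + m
    chunks <- c(chunks, m)
    recall <- c(recall, frontier)
  }
  structure(list(
    chunk_sizes = chunks,
    cumulative_recall = recall,
    iterations_to_complete = if (frontier >= n) it else NA_integer_,
    n = n, C = cfg$C
  ), class = "learning_trace")
}

#' @export
print.learning_trace <- function(x, ...) {
  done <- if (is.na(x$iterations_to_complete)) "not reached"
          else sprintf("%d iterations", x$iterations_to_complete)
  cat(sprintf("Chunk-learning trace: n = %d, C = %g, complete in %s\n",
              x$n, x$C, done))
  cat("  chunk sizes:       ", paste(x$chunk_sizes, collapse = " "), "\n")
  cat("  cumulative recall: ", paste(x$cumulative_recall, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.learning_trace <- function(x, ...) {
  data.frame(iteration = seq_along(x$chunk_sizes),
             chunk_size = x$chunk_sizes,
             cumulative_recall = x$cumulative_recall)
}

#' Plot a chunk-learning trace
#'
#' Cumulative recall (items) against learning iteration.
#'
#' @param x A `learning_trace`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.learning_trace <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::plot(df$iteration, df$cumulative_recall, type = "b",
                 xlab = "Iteration", ylab = "Cumulative recall (items)",
                 ylim = c(0, x$n), ...)
  graphics::abline(h = x$n, lty = 3)
  invisible(x)
}

#' Write a learning trace as tidy CSV
#'
#' Columns: iteration, chunk_size, cumulative_recall.
#'
#' @param x A `learning_trace`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_learning_trace <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
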