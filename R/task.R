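# The eight-target centre-out sequence-learning task: geometry, trial
# schedules, sequence generation, recall scoring and trial-termination
# semantics. Coordinates are mm, origin at screen centre, x rightward,
# y upward.

DIRECTIONS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

direction_unit <- function(tok) {
  ang <- c(N = 90, NE = 45, E = 0, SE = -45, S = -90, SW = -135,
           W = 180, NW = 135)[tok]
  rad <- ang * pi / 180
  c(cos(rad), sin(rad))
}

#' Screen layout of the sequence-learning task
#'
#' One central box surrounded by eight identical target boxes at the
#' compass directions.
#'
#' @param center_side Side of the central box (mm), default 25.
#' @param target_side Side of each target box (mm), default 25.
#' @param distance Centre-to-target distance (mm), default 80. The task
#'   description never fixes this, so it is a configurable layout default;
#'   every movement amplitude derives from it.
#' @return An object of class `target_layout` with a `targets` matrix of
#'   centre coordinates (mm), rows named by direction.
#' @export
target_layout <- function(center_side = 25, target_side = 25,
                          distance = 80) {
  if (distance <= (center_side + target_side) / 2 * sqrt(2))
    stop_domain("targets would overlap the central box")
  targets <- t(vapply(DIRECTIONS, function(d) distance * direction_unit(d),
                      numeric(2)))
  colnames(targets) <- c("x", "y")
  structure(list(center_side = center_side, target_side = target_side,
                 distance = distance, targets = targets),
            class = "target_layout")
}

#' @export
print.target_layout <- function(x, ...) {
  cat(sprintf(
    "Eight-target layout: centre box %g mm, targets %g mm at %g mm\n",
    x$center_side, x$target_side, x$distance))
  invisible(x)
}

#' Alternating training/test trial schedule
#'
#' Each repetition contributes one training trial followed by one test
#' trial, so `repetitions = 14` gives the 28-trial session and
#' `repetitions = 10` the 20-trial sessions.
#'
#' @param repetitions Number of training/test pairs (>= 0).
#' @return A data.frame with columns `trial_index`, `trial_type`
#'   ("training"/"test") and `repetition`.
#' @export
build_schedule <- function(repetitions) {
  if (!is.numeric(repetitions) || length(repetitions) != 1 ||
      repetitions < 0 || repetitions != as.integer(repetitions))
    stop_domain("repetitions must be a non-negative integer")
  repetitions <- as.integer(repetitions)
  n <- 2L * repetitions
  data.frame(
    trial_index = seq_len(n),
    trial_type = rep(c("training", "test"), repetitions),
    repetition = rep(seq_len(repetitions), each = 2L)
  )[seq_len(n), , drop = FALSE]
}

#' Read / write a trial schedule as CSV
#'
#' @param schedule data.frame from [build_schedule()].
#' @param path CSV file.
#' @return `read_schedule`: the schedule data.frame.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "trial_type", "repetition")
  if (!all(need %in% names(df)))
    stop_domain("not a schedule file: needs columns ",
                paste(need, collapse = ", "))
  df
}

#' Generate an irregular direction sequence
#'
#' Seeded pseudo-random tokens over the eight compass directions; the
#' default constraint forbids immediate repeats (each next token uniform
#' over the other seven directions), giving the irregular feel of the task
#' sequences. The same seed always yields the same sequence, so one
#' sequence can be shared across simulated participants.
#'
#' @param length Sequence length (>= 1), e.g. 30 or 16.
#' @param seed Optional integer seed.
#' @param no_repeat Forbid equal adjacent tokens (default `TRUE`).
#' @return Character vector of direction tokens.
#' @export
generate_sequence <- function(length, seed = NULL, no_repeat = TRUE) {
  if (length < 1) stop_domain("length must be >= 1")
  with_seed(seed, {
    toks <- character(length)
    toks[1] <- sample(DIRECTIONS, 1)
    if (length > 1) for (i in 2:length) {
      pool <- if (no_repeat) setdiff(DIRECTIONS, toks[i - 1]) else DIRECTIONS
      toks[i] <- sample(pool, 1)
    }
    toks
  })
}

#' Read / write sequence files (one direction token per line)
#'
#' @param path Plain-text file.
#' @return `read_sequence`: character vector of tokens.
#' @export
read_sequence <- function(path) {
  toks <- readLines(path)
  toks <- toks[nzchar(toks)]
  bad <- setdiff(unique(toks), DIRECTIONS)
  if (length(bad))
    stop_domain("unknown direction token(s): ", paste(bad, collapse = ", "))
  toks
}

#' @rdname read_sequence
#' @param tokens Character vector of direction tokens.
#' @export
write_sequence <- function(tokens, path) {
  writeLines(tokens, path)
  invisible(path)
}

#' Score recalled moves against the true sequence
#'
#' `prefix` mode (default) counts the longest correct prefix: the first
#' error ends successful recall. `positional` mode counts every position
#' where the response matches the truth, with no deduction for errors.
#' Both are bounded by the truth length.
#'
#' @param response Character vector of recalled tokens (may be empty).
#' @param truth Character vector, the true sequence.
#' @param mode `"prefix"` or `"positional"`.
#' @return CR, the number of moves recalled in correct serial order.
#' @export
score_recall <- function(response, truth, mode = c("prefix", "positional")) {
  mode <- match.arg(mode)
  n <- min(length(response), length(truth))
  if (n == 0L) return(0L)
  match_vec <- response[seq_len(n)] == truth[seq_len(n)]
  if (mode == "prefix") {
    miss <- which(!match_vec)
    if (length(miss)) as.integer(miss[1] - 1L) else as.integer(n)
  } else {
    as.integer(sum(match_vec))
  }
}

#' Detect participant-controlled trial termination
#'
#' A trial ends when the cursor dwells inside the central box for more than
#' `dwell` seconds (strict inequality). Returns the index of the first
#' sample at which the running dwell exceeds the threshold, or the last
#' index if no such dwell occurs.
#'
#' @param trace data.frame with columns `t_s`, `x_mm`, `y_mm`, timestamps
#'   sorted increasing.
#' @param layout A [target_layout()] defining the central box.
#' @param dwell Dwell threshold in seconds, default 4.
#' @return Integer row index of trial end.
#' @export
detect_termination <- function(trace, layout = target_layout(), dwell = 4) {
  if (is.unsorted(trace$t_s)) stop_domain("timestamps must be sorted")
  half <- layout$center_side / 2
  inside <- abs(trace$x_mm) <= half & abs(trace$y_mm) <= half
  run_start <- NA_real_
  for (i in seq_len(nrow(trace))) {
    if (inside[i]) {
      if (is.na(run_start)) run_start <- trace$t_s[i]
      if (trace$t_s[i] - run_start > dwell) return(i)
    } else {
      run_start <- NA_real_
    }
  }
  nrow(trace)
}
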