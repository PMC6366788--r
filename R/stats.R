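# Behavioural outcome measures: correct recall (CR), recall movement time
# (MT_r), path length (PL), training-trial duration (MT_t), first/last-five
# block means, chunk increments, and the reported-percentage arithmetic.

#' Path length of a cursor trace
#'
#' Total distance travelled (mm): sum of Euclidean distances between
#' consecutive samples over the whole trial. Longer paths indicate error
#' corrections.
#'
#' @param trace data.frame with columns `x_mm`, `y_mm` (>= 2 rows).
#' @return Path length in mm.
#' @export
compute_PL <- function(trace) {
  if (nrow(trace) < 2) stop_domain("trace needs at least 2 samples")
  sum(sqrt(diff(trace$x_mm)^2 + diff(trace$y_mm)^2))
}

#' Mean recall movement time
#'
#' Mean duration of outbound centre-to-target moves in a test trial;
#' return moves are not part of the measure. `NA` (not zero) when the trial
#' contains no moves.
#'
#' @param events data.frame of trial events with columns `trial_type`,
#'   `move_start_s`, `move_end_s`; rows are outbound moves.
#' @return Mean move duration in seconds, or `NA_real_`.
#' @export
compute_MT_r <- function(events) {
  ev <- events[events$trial_type == "test", , drop = FALSE]
  if (nrow(ev) == 0) return(NA_real_)
  mean(ev$move_end_s - ev$move_start_s)
}

#' Training-trial duration
#'
#' Time from the first to the last event of a training trial.
#'
#' @param events data.frame with columns `move_start_s`, `move_end_s`
#'   for one training trial.
#' @return Duration in seconds.
#' @export
compute_MT_t <- function(events) {
  if (nrow(events) == 0) stop_domain("empty trial")
  max(events$move_end_s) - min(events$move_start_s)
}

#' First-five / last-five block means
#'
#' Mean of a per-trial measure over the first five (F5) or last five (L5)
#' trials of the relevant type: first a window mean per participant, then
#' the condition mean of participant means.
#'
#' @param session data.frame with one row per participant x trial,
#'   containing `participant_id`, `trial_index` (order within the relevant
#'   trial type) and the measure column.
#' @param measure Name of the measure column (e.g. `"CR"`, `"MT_r"`).
#' @param window `"F5"` or `"L5"`.
#' @return List with `condition_mean` and a data.frame
#'   `participant_means` (`participant_id`, `mean`).
#' @export
block_means <- function(session, measure, window = c("F5", "L5")) {
  window <- match.arg(window)
  if (!measure %in% names(session)) stop_domain("unknown measure: ", measure)
  per <- split(session, session$participant_id)
  pm <- vapply(per, function(df) {
    df <- df[order(df$trial_index), , drop = FALSE]
    n <- nrow(df)
    if (n < 5) stop_domain("need at least 5 trials per participant")
    idx <- if (window == "F5") 1:5 else (n - 4):n
    mean(df[[measure]][idx])
  }, numeric(1))
  list(condition_mean = mean(pm),
       participant_means = data.frame(participant_id = names(pm),
                                      mean = unname(pm)))
}

#' Trial-over-trial chunk increments of recall
#'
#' The increase in CR from one test trial to the next, the behavioural
#' signature of chunked encoding. Default mode takes increments of the
#' running maximum of CR, which is non-negative by construction (a trial
#' where recall dips does not count as negative chunking); `"raw"` takes
#' plain successive differences. The first increment is measured from 0.
#'
#' @param CR Numeric vector, per-test-trial CR for one participant.
#' @param mode `"running_max"` (default) or `"raw"`.
#' @return Numeric vector of per-trial increments, same length as `CR`.
#' @export
chunk_increments <- function(CR, mode = c("running_max", "raw")) {
  mode <- match.arg(mode)
  if (length(CR) < 2) stop_domain("need at least 2 trials")
  base <- if (mode == "running_max") cummax(CR) else CR
  diff(c(0, base))
}

#' Proportion of the sequence recalled
#'
#' `100 * CR / L`, reported both exactly and rounded (half up) to the
#' nearest integer percent, the convention used for reported recall
#' percentages (e.g. 8 of 30 -> 26.67 -> 27%).
#'
#' @param CR Mean number of items recalled.
#' @param L Sequence length (> 0).
#' @return List with `percent` (integer-rounded) and `exact`.
#' @export
proportion_recalled <- function(CR, L) {
  if (L <= 0) stop_domain("L must be > 0")
  exact <- 100 * CR / L
  list(percent = round_half_up(exact), exact = exact)
}

#' Between-hand drop-off in recall
#'
#' The preferred-minus-non-preferred recall difference expressed as a
#' percentage of the sequence length: `100 * (pref - nonpref) / L`
#' (2 items of a 16-move sequence -> 12.5%).
#'
#' @param pref_CR Items recalled with the preferred hand.
#' @param nonpref_CR Items recalled with the non-preferred hand.
#' @param L Sequence length (> 0).
#' @return Percent drop-off.
#' @export
hand_drop <- function(pref_CR, nonpref_CR, L) {
  if (L <= 0) stop_domain("L must be > 0")
  100 * (pref_CR - nonpref_CR) / L
}
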