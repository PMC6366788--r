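# Synthetic cohort generator.
#
# Produces participants, sessions, trial events and 2-D cursor traces with
# the structure the analysis pipeline assumes: alternating training/test
# trials over an 8-target layout, recall that grows in chunks limited by
# working-memory capacity, movement times following the speed-accuracy law,
# and traces whose path length grows with corrective submovements. Group
# defaults encode the qualitative age contrast (older adults: slower and
# noisier movements, hence higher element loads, and a smaller capacity);
# hand and mouse-orientation difficulty scale the informational
# coefficients.

#' Default generative parameters for an age group
#'
#' Younger adults: faster, cleaner movements (smaller a, b, |c|), few
#' corrective submovements, capacity around four buffer units. Older
#' adults: slower movements with more corrections, hence larger per-element
#' loads, and a capacity around two. With the default load scale these
#' defaults put younger early-trial chunk increments in the 3-5 item range
#' and older increments near one item per trial.
#'
#' @param group `"younger"` or `"older"`.
#' @return Named list of group-mean parameters: `a`, `b`, `c` (movement
#'   law), `C` (capacity, buffer units), `sigma` (positional jitter, mm),
#'   `lambda` (corrective submovements per move), `recall_sd` (trial-level
#'   recall noise, items).
#' @export
default_group_params <- function(group = c("younger", "older")) {
  group <- match.arg(group)
  if (group == "younger")
    list(a = 0.30, b = 0.15, c = -0.10, C = 4.0,
         sigma = 0.5, lambda = 0.2, recall_sd = 0.75)
  else
    list(a = 0.50, b = 0.25, c = -0.15, C = 2.0,
         sigma = 1.5, lambda = 1.0, recall_sd = 0.75)
}

#' A synthetic participant profile
#'
#' @param id Participant identifier.
#' @param group `"younger"` or `"older"`.
#' @param params Named list as from [default_group_params()].
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(id, group, params = default_group_params(group)) {
  group <- match.arg(group, c("younger", "older"))
  stopifnot(all(c("a", "b", "c", "C", "sigma", "lambda", "recall_sd")
                %in% names(params)))
  if (params$C <= 0 || params$sigma < 0 || params$lambda < 0 ||
      params$recall_sd < 0)
    stop_domain("invalid profile parameters")
  structure(c(list(id = id, group = group), params),
            class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf(
    "Participant %s (%s): a=%.2f b=%.3f c=%.3f C=%.2f sigma=%.2f lambda=%.2f\n",
    x$id, x$group, x$a, x$b, x$c, x$C, x$sigma, x$lambda))
  invisible(x)
}

#' Cohort configuration
#'
#' Group sizes and between-participant variability. Parameters are drawn
#' from normal distributions around the group means with coefficient of
#' variation `cv`, truncated at small positive bounds so every draw is a
#' valid profile.
#'
#' @param n_younger,n_older Group sizes (>= 1, either may be 0).
#' @param cv Coefficient of variation of parameter draws, default 0.1;
#'   0 gives all-identical profiles at the group means.
#' @param engine Generative engine for recall growth:
#'   `"chunk_buffer"` (deterministic capacity-limited chunking, default)
#'   or `"wm_qlearning"` (the reinforcement-learning agent).
#' @param seed Integer seed for cohort sampling.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_younger = 10, n_older = 10, cv = 0.1,
                          engine = c("chunk_buffer", "wm_qlearning"),
                          seed = 1) {
  engine <- match.arg(engine)
  if (n_younger < 0 || n_older < 0 || n_younger + n_older < 1)
    stop_domain("need at least one participant")
  if (cv < 0 || cv >= 1) stop_domain("cv must be in [0, 1)")
  structure(list(n_younger = n_younger, n_older = n_older, cv = cv,
                 engine = engine, seed = seed),
            class = "cohort_config")
}

# truncated-normal draw around mean m with sd cv*|m|, kept above lo
rtrunc <- function(m, cv, lo) {
  if (cv == 0) return(m)
  max(lo, stats::rnorm(1, m, cv * abs(m)))
}

#' Sample a cohort of participant profiles
#'
#' Seeded and reproducible; with `cv = 0` every profile equals its group
#' means, and group-level orderings (younger capacity above older, older
#' loads above younger) hold in expectation for `cv > 0`.
#'
#' @param cfg A [cohort_config()].
#' @return List of [participant_profile()]s.
#' @export
sample_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) stop_domain("cfg must be a cohort_config")
  with_seed(cfg$seed, {
    mk <- function(group, i) {
      gm <- default_group_params(group)
      p <- list(
        a = rtrunc(gm$a, cfg$cv, 0.05),
        b = rtrunc(gm$b, cfg$cv, 0.01),
        c = -rtrunc(abs(gm$c), cfg$cv, 0.01),
        C = rtrunc(gm$C, cfg$cv, 0.25),
        sigma = rtrunc(gm$sigma, cfg$cv, 0),
        lambda = rtrunc(gm$lambda, cfg$cv, 0),
        recall_sd = gm$recall_sd)
      participant_profile(sprintf("%s%02d", substr(group, 1, 1), i), group, p)
    }
    c(lapply(seq_len(cfg$n_younger), function(i) mk("younger", i)),
      lapply(seq_len(cfg$n_older), function(i) mk("older", i)))
  })
}

#' Experiment specification
#'
#' Sequence length, number of training/test repetitions and screen layout
#' for the three experiment designs: `exp1` (30 moves, 14 repetitions),
#' `exp2` and `exp3` (16 moves, 10 repetitions).
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param sequence_seed Seed for the shared session sequence (all simulated
#'   participants learn the same sequence), default 101.
#' @param layout A [target_layout()].
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(experiment = c("exp1", "exp2", "exp3"),
                            sequence_seed = 101, layout = target_layout()) {
  experiment <- match.arg(experiment)
  len <- if (experiment == "exp1") 30L else 16L
  reps <- if (experiment == "exp1") 14L else 10L
  structure(list(experiment = experiment, length = len, repetitions = reps,
                 sequence_seed = sequence_seed, layout = layout),
            class = "experiment_spec")
}

# condition-difficulty multiplier: non-preferred hand and sideways mouse
# scale the informational coefficients and the correction rate
condition_multiplier <- function(hand, orientation, mult = 1.3) {
  m <- 1
  if (hand == "nonpreferred") m <- m * mult
  if (orientation == "sideways") m <- m * mult
  m
}

# skill parameters for one condition of one profile
condition_skill <- function(profile, hand, orientation, mult = 1.3) {
  m <- condition_multiplier(hand, orientation, mult)
  skill_params(profile$a, profile$b * m, profile$c * m)
}

# minimum-jerk position profile on [0, 1]
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# render one straight centre->target (or back) move as trace samples;
# corrective submovements add out-and-back perpendicular detours, each
# adding exactly 2*amp of path length
render_move <- function(from, to, duration, t0, hz, n_corr = 0,
                        corr_amp = 4, sigma = 0) {
  n <- max(2L, ceiling(duration * hz))
  tau <- seq(0, 1, length.out = n)
  pos <- outer(min_jerk(tau), to - from)
  xy <- sweep(pos, 2, from, "+")
  t <- t0 + tau * duration
  if (n_corr > 0) {
    dir <- (to - from) / sqrt(sum((to - from)^2))
    perp <- c(-dir[2], dir[1])
    for (j in seq_len(n_corr)) {
      at <- sample(seq(max(2, floor(0.3 * n)), floor(0.9 * n)), 1)
      detour <- rbind(xy[at, ] + corr_amp * perp, xy[at, ])
      xy <- rbind(xy[seq_len(at), , drop = FALSE], detour,
                  xy[seq(at + 1, n), , drop = FALSE])
      t <- c(t[seq_len(at)], t[at] + c(1, 2) * 0.05, t[seq(at + 1, n)] + 0.1)
      n <- n + 2L
    }
  }
  if (sigma > 0 && n > 2) {
    mid <- 2:(n - 1) # endpoints pinned so moves start/end on the boxes
    xy[mid, ] <- xy[mid, ] + matrix(stats::rnorm(2 * length(mid), 0, sigma),
                                    ncol = 2)
  }
  list(t = t, x = xy[, 1], y = xy[, 2], t_end = t[n])
}

#' Generate one synthetic session (events, traces, outcomes)
#'
#' Simulates a whole alternating training/test session for one participant
#' and one condition. Recall growth comes from the chosen engine: the
#' chunk-buffer engine advances one buffer iteration per training trial,
#' the RL engine runs one cued training trial of the working-memory
#' Q-learner. Each move is rendered as a straight minimum-jerk trace of
#' duration given by the movement-time law, plus Poisson-count corrective
#' submovements and Gaussian positional jitter; test trials end with a
#' centre dwell exceeding the termination threshold.
#'
#' @param profile A [participant_profile()].
#' @param spec An [experiment_spec()].
#' @param hand `"preferred"` or `"nonpreferred"`.
#' @param orientation `"regular"` or `"sideways"`.
#' @param seed Seed for this session's noise.
#' @param traces Render cursor traces (default `TRUE`; turn off for large
#'   parameter-recovery sweeps where only recall is needed).
#' @param hz Trace sampling rate (samples/s), default 50.
#' @param load_scale Buffer units per second of informational processing
#'   (the `k` of [element_load()]), default 2.
#' @param guess_tail If `TRUE`, test responses append random guesses after
#'   the learned prefix (participants could keep guessing); default off.
#' @param noise If `FALSE`, all stochastic components (recall noise,
#'   jitter, corrective submovements) are disabled.
#' @return A `wmseq_session`: list with `sequence`, `events`, `traces`
#'   (or `NULL`), `outcomes` (per-trial rows: trial_index, trial_type, CR,
#'   MT_r, PL, MT_t), `profile`, `spec`, `hand`, `orientation`, `seed`.
#' @export
generate_session <- function(profile, spec, hand = "preferred",
                             orientation = "regular", seed = 1,
                             traces = TRUE, hz = 50, load_scale = 2,
                             guess_tail = FALSE, noise = TRUE) {
  hand <- match.arg(hand, c("preferred", "nonpreferred"))
  orientation <- match.arg(orientation, c("regular", "sideways"))
  truth <- generate_sequence(spec$length, seed = spec$sequence_seed)
  sk <- condition_skill(profile, hand, orientation)
  layout <- spec$layout
  mv <- movement(A = layout$distance, W = layout$target_side)
  mt <- movement_time(mv, sk)
  load <- element_load(mv, sk, k = load_scale)
  lambda <- if (noise) profile$lambda *
    condition_multiplier(hand, orientation) else 0
  sigma <- if (noise) profile$sigma else 0
  recall_sd <- if (noise) profile$recall_sd else 0

  with_seed(seed, {
    # recall frontier after each training trial, by engine
    reps <- spec$repetitions
    frontier <- chunk_engine_frontiers(profile, truth, load, reps)
    schedule <- build_schedule(reps)
    dwell_s <- 0.3
    ev_rows <- list(); tr_rows <- list(); out_rows <- list()
    for (i in seq_len(nrow(schedule))) {
      ttype <- schedule$trial_type[i]
      rep_i <- schedule$repetition[i]
      if (ttype == "training") {
        toks <- truth
        cue <- truth
      } else {
        learned <- frontier[rep_i]
        cr_obs <- learned
        if (recall_sd > 0)
          cr_obs <- max(0, min(spec$length,
                               round(learned + stats::rnorm(1, 0, recall_sd))))
        toks <- truth[seq_len(cr_obs)]
        if (guess_tail && cr_obs < spec$length) {
          extra <- stats::rpois(1, 2)
          toks <- c(toks, sample(DIRECTIONS, min(extra, spec$length - cr_obs),
                                 replace = TRUE))
        }
        cue <- rep(NA_character_, length(toks))
      }
      t0 <- 0
      trial_ev <- list(); trial_tr <- list()
      if (length(toks)) for (m in seq_along(toks)) {
        tgt <- layout$targets[toks[m], ]
        n_corr <- if (lambda > 0) stats::rpois(1, lambda) else 0L
        out <- render_move(c(0, 0), tgt, mt, t0, hz, n_corr,
                           sigma = sigma)
        move_start <- t0; move_end <- out$t_end
        back <- render_move(tgt, c(0, 0), mt, move_end, hz, 0, sigma = sigma)
        t0 <- back$t_end
        trial_ev[[m]] <- data.frame(
          trial_id = i, trial_type = ttype, move_index = m,
          cue_token = cue[m], response_token = toks[m],
          move_start_s = move_start, move_end_s = move_end,
          stringsAsFactors = FALSE)
        if (traces) {
          trial_tr[[m]] <- data.frame(
            trial_id = i,
            t_s = c(out$t, back$t),
            x_mm = c(out$x, back$x), y_mm = c(out$y, back$y))
        }
        # inter-move dwell at centre
        if (traces) {
          td <- seq(t0 + 1 / hz, t0 + dwell_s, by = 1 / hz)
          trial_tr[[length(trial_tr) + 1L]] <- data.frame(
            trial_id = i, t_s = td, x_mm = 0, y_mm = 0)
        }
        t0 <- t0 + dwell_s
      }
      if (traces && ttype == "test") { # terminating dwell > 4 s
        td <- seq(t0 + 1 / hz, t0 + 4.5, by = 1 / hz)
        trial_tr[[length(trial_tr) + 1L]] <- data.frame(
          trial_id = i, t_s = td, x_mm = 0, y_mm = 0)
      }
      ev <- if (length(trial_ev)) do.call(rbind, trial_ev) else NULL
      tr <- if (traces && length(trial_tr)) do.call(rbind, trial_tr) else NULL
      ev_rows[[i]] <- ev
      tr_rows[[i]] <- tr
      # per-trial outcomes via the analysis functions
      out_rows[[i]] <- data.frame(
        trial_index = i, trial_type = ttype, repetition = rep_i,
        CR = if (ttype == "test")
          as.integer(score_recall(toks, truth)) else NA_integer_,
        MT_r = if (ttype == "test" && !is.null(ev)) compute_MT_r(ev)
               else NA_real_,
        PL = if (ttype == "training" && !is.null(tr)) compute_PL(tr)
             else NA_real_,
        MT_t = if (ttype == "training" && !is.null(ev)) compute_MT_t(ev)
               else NA_real_)
    }
    structure(list(
      sequence = truth,
      events = do.call(rbind, ev_rows),
      traces = if (traces) do.call(rbind, tr_rows) else NULL,
      outcomes = do.call(rbind, out_rows),
      profile = profile, spec = spec, hand = hand,
      orientation = orientation, seed = seed,
      element_load = load, movement_time = mt
    ), class = "wmseq_session")
  })
}

# per-repetition recall frontier from the generative engine
chunk_engine_frontiers <- function(profile, truth, load, reps) {
  engine <- attr(profile, "engine")
  if (is.null(engine)) engine <- "chunk_buffer"
  n <- length(truth)
  if (engine == "wm_qlearning") {
    tasks <- tasks_from_sequence(truth)
    sess <- simulate_rl_experiment(
      tasks, capacity = max(0, round(profile$C)), n_trials = reps,
      p_err = min(0.5, profile$lambda / (1 + profile$lambda)))
    return(pmin(sess$CR, n))
  }
  tr <- simulate_learning(element_sequence(rep(load, n)),
                          buffer_config(profile$C), max_iters = reps)
  fr <- tr$cumulative_recall
  if (length(fr) < reps) fr <- c(fr, rep(n, reps - length(fr)))
  fr[seq_len(reps)]
}

#' @export
print.wmseq_session <- function(x, ...) {
  cat(sprintf(
    "Synthetic session: %s, %s/%s hand %s, %d-move sequence, %d trials\n",
    x$profile$id, x$spec$experiment, x$orientation, x$hand,
    x$spec$length, nrow(x$outcomes)))
  tst <- x$outcomes[x$outcomes$trial_type == "test", ]
  cat("  CR by test trial:", paste(tst$CR, collapse = " "), "\n")
  invisible(x)
}

#' Write a synthetic session to a directory
#'
#' Writes `sequence.txt` (one token per line), `events.csv`, `traces.csv`
#' (if present), `outcomes.csv` and `manifest.json` (condition labels,
#' seed, profile parameters) for provenance.
#'
#' @param session A `wmseq_session`.
#' @param dir Directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sequence(session$sequence, file.path(dir, "sequence.txt"))
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(session$traces))
    utils::write.csv(session$traces, file.path(dir, "traces.csv"),
                     row.names = FALSE)
  utils::write.csv(session$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  pr <- session$profile
  manifest <- list(
    participant = pr$id, group = pr$group,
    params = pr[c("a", "b", "c", "C", "sigma", "lambda", "recall_sd")],
    experiment = session$spec$experiment,
    sequence_seed = session$spec$sequence_seed,
    hand = session$hand, orientation = session$orientation,
    seed = session$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic session from a directory
#'
#' @param dir Directory written by [write_session()].
#' @return A `wmseq_session` (traces `NULL` if not on disk).
#' @export
read_session <- function(dir) {
  need <- file.path(dir, c("sequence.txt", "events.csv", "outcomes.csv",
                           "manifest.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop_domain("missing session file(s): ", paste(missing, collapse = ", "))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  profile <- participant_profile(man$participant, man$group, man$params)
  tr_path <- file.path(dir, "traces.csv")
  structure(list(
    sequence = read_sequence(file.path(dir, "sequence.txt")),
    events = utils::read.csv(file.path(dir, "events.csv"),
                             stringsAsFactors = FALSE),
    traces = if (file.exists(tr_path)) utils::read.csv(tr_path) else NULL,
    outcomes = utils::read.csv(file.path(dir, "outcomes.csv"),
                               stringsAsFactors = FALSE),
    profile = profile,
    spec = experiment_spec(man$experiment, sequence_seed = man$sequence_seed),
    hand = man$hand, orientation = man$orientation, seed = man$seed
  ), class = "wmseq_session")
}

#' Simulate a cohort into a tidy session table
#'
#' Runs [generate_session()] for every sampled participant and requested
#' condition and stacks the per-trial outcomes into one tidy table.
#'
#' @param cfg A [cohort_config()].
#' @param spec An [experiment_spec()].
#' @param hands Character vector of hand conditions to run.
#' @param orientations Character vector of orientation conditions to run.
#' @param traces Render traces (default `FALSE`: outcome rows for training
#'   trials then omit PL).
#' @param ... Further arguments to [generate_session()].
#' @return data.frame with columns participant_id, group, hand,
#'   orientation, trial_index, trial_type, repetition, CR, MT_r, PL, MT_t.
#' @export
simulate_cohort <- function(cfg, spec, hands = "preferred",
                            orientations = "regular", traces = FALSE, ...) {
  profiles <- sample_cohort(cfg)
  rows <- list()
  k <- 0L
  for (p in profiles) {
    if (cfg$engine == "wm_qlearning") attr(p, "engine") <- "wm_qlearning"
    for (h in hands) for (o in orientations) {
      k <- k + 1L
      s <- generate_session(p, spec, hand = h, orientation = o,
                            seed = cfg$seed + 7919L * k,
                            traces = traces, ...)
      out <- s$outcomes
      out$participant_id <- p$id
      out$group <- p$group
      out$hand <- h
      out$orientation <- o
      rows[[k]] <- out
    }
  }
  df <- do.call(rbind, rows)
  df[, c("participant_id", "group", "hand", "orientation", "trial_index",
         "trial_type", "repetition", "CR", "MT_r", "PL", "MT_t")]
}

#' Average chunk increments across participants, per test trial
#'
#' For each participant the CR series over test trials is reduced to
#' per-trial increments with [chunk_increments()]; increments are then
#' averaged across participants within each condition cell, giving the
#' per-trial average number of additional items recalled.
#'
#' @param session_table Output of [simulate_cohort()].
#' @param mode Passed to [chunk_increments()].
#' @return data.frame: group, hand, orientation, trial (test-trial number),
#'   mean_increment.
#' @export
average_increments <- function(session_table, mode = "running_max") {
  tst <- session_table[session_table$trial_type == "test", , drop = FALSE]
  cells <- split(tst, list(tst$group, tst$hand, tst$orientation), drop = TRUE)
  out <- lapply(cells, function(cell) {
    per <- split(cell, cell$participant_id)
    incs <- vapply(per, function(df) {
      df <- df[order(df$trial_index), ]
      chunk_increments(df$CR, mode = mode)
    }, numeric(nrow(per[[1]])))
    data.frame(group = cell$group[1], hand = cell$hand[1],
               orientation = cell$orientation[1],
               trial = seq_len(nrow(as.matrix(incs))),
               mean_increment = rowMeans(as.matrix(incs)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
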