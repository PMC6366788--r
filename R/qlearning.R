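# Model-free reinforcement-learning instantiation of working-memory-limited
# sequence learning.
#
# Each target (sub-goal) of the movement sequence is its own deterministic
# grid world: states are grid cells, actions move one cell N/E/S/W (moves
# off the grid leave the agent in place), every action costs -1, and an
# episode ends at the target cell or after a step cap. A tabular q-function
# per sub-goal is the agent's long-term memory. During a training trial a
# teacher policy demonstrates each cued sub-goal; every transition generates
# a proposed Q-learning increment, which enters a fixed-capacity working-
# memory queue only if it would change the value function by more than a
# significance threshold. The queue is flushed to the q-tables once at the
# end of the trial, so between flushes the value function is frozen.
# Test trials read out greedy recall: a sub-goal is recalled if the greedy
# policy reaches the target within a step budget, and recall stops at the
# first failure.

ACTIONS <- c("N", "E", "S", "W")
ACTION_DX <- c(N = 0L, E = 1L, S = 0L, W = -1L)
ACTION_DY <- c(N = 1L, E = 0L, S = -1L, W = 0L)

#' A deterministic grid-world task for one sub-goal
#'
#' @param width,height Grid dimensions in cells.
#' @param start Start cell, integer `c(x, y)` with x rightward (E), y
#'   upward (N), both 1-based.
#' @param target Target cell, same coding; must differ from `start`.
#' @param T Step cap per episode; must be at least the Manhattan distance
#'   from start to target. Default `2 * (width + height)`.
#' @return An object of class `grid_task`.
#' @export
grid_task <- function(width, height, start, target,
                      T = 2 * (width + height)) {
  width <- as.integer(width); height <- as.integer(height)
  start <- as.integer(start); target <- as.integer(target)
  stopifnot(width >= 1, height >= 1,
            length(start) == 2, length(target) == 2)
  in_grid <- function(s) s[1] >= 1 && s[1] <= width && s[2] >= 1 && s[2] <= height
  if (!in_grid(start) || !in_grid(target))
    stop_domain("start and target must lie inside the grid")
  if (all(start == target)) stop_domain("start must differ from target")
  d <- sum(abs(start - target))
  if (T < d) stop_domain("step cap T must be >= Manhattan distance")
  structure(list(width = width, height = height, start = start,
                 target = target, T = as.integer(T), dist = d),
            class = "grid_task")
}

#' @export
print.grid_task <- function(x, ...) {
  cat(sprintf("Grid task %dx%d: start (%d,%d) -> target (%d,%d), d = %d, T = %d\n",
              x$width, x$height, x$start[1], x$start[2],
              x$target[1], x$target[2], x$dist, x$T))
  invisible(x)
}

state_id <- function(task, s) (s[2] - 1L) * task$width + s[1]

#' Fresh q-table for one grid task
#'
#' One row per cell, one column per action (N, E, S, W), uniformly
#' initialised (default 0): the naive agent values all state-action pairs
#' equally.
#'
#' @param task A [grid_task()].
#' @param init Initial value for every entry, default 0.
#' @return A numeric matrix of class `q_table`.
#' @export
new_q_table <- function(task, init = 0) {
  q <- matrix(init, nrow = task$width * task$height, ncol = 4,
              dimnames = list(NULL, ACTIONS))
  class(q) <- c("q_table", class(q))
  q
}

#' One deterministic environment step
#'
#' Moves one cell in the chosen direction; a move that would leave the grid
#' leaves the agent in its current cell. Reward is -1 per action; the
#' transition is terminal when the next state is the target.
#'
#' @param task A [grid_task()].
#' @param s Current cell `c(x, y)`; must be inside the grid.
#' @param a Action, one of `"N"`, `"E"`, `"S"`, `"W"`.
#' @return A list `(s, a, r, s_next, terminal)` with `r = -1`.
#' @export
env_step <- function(task, s, a) {
  s <- as.integer(s)
  if (s[1] < 1 || s[1] > task$width || s[2] < 1 || s[2] > task$height)
    stop_domain("state outside grid")
  a <- match.arg(a, ACTIONS)
  nxt <- c(s[1] + ACTION_DX[[a]], s[2] + ACTION_DY[[a]])
  if (nxt[1] < 1 || nxt[1] > task$width || nxt[2] < 1 || nxt[2] > task$height)
    nxt <- s
  list(s = s, a = a, r = -1,
       s_next = nxt, terminal = all(nxt == task$target))
}

#' Proposed Q-learning increment for one transition
#'
#' `alpha * (r + max_a' q(s', a') - q(s, a))`, with the bootstrap term 0 at
#' a terminal next state and an undiscounted return. The q-table is not
#' mutated; mutation happens only when the working-memory queue is flushed.
#'
#' @param q A `q_table`.
#' @param task The [grid_task()] the table belongs to.
#' @param tr A transition from [env_step()].
#' @param alpha Learning rate in (0, 1]; default 1 (exact in a
#'   deterministic environment).
#' @return The proposed increment (return units).
#' @export
propose_update <- function(q, task, tr, alpha = 1) {
  if (alpha <= 0 || alpha > 1) stop_domain("alpha must be in (0, 1]")
  boot <- if (tr$terminal) 0 else max(q[state_id(task, tr$s_next), ])
  unname(alpha * (tr$r + boot - q[state_id(task, tr$s), match(tr$a, ACTIONS)]))
}

#' Fixed-capacity significance-gated working-memory queue
#'
#' Holds proposed value-function updates during a trial. An update is
#' admitted only if the queue has free space and its magnitude exceeds the
#' significance threshold `theta` (strict inequality). With
#' `dedup = TRUE` (default) a new update for a state-action pair already in
#' the queue replaces the pending one (a recency effect) and needs no free
#' slot; with `dedup = FALSE` duplicates coexist and are applied in arrival
#' order at flush.
#'
#' @param capacity Maximum number of pending items (>= 0, may be `Inf`).
#' @param theta Significance threshold in return units, default `1e-6`
#'   (any materially nonzero change is significant).
#' @param dedup Replace pending updates for a repeated state-action pair.
#' @return An object of class `wm_queue`.
#' @export
wm_queue <- function(capacity, theta = 1e-6, dedup = TRUE) {
  if (capacity < 0) stop_domain("capacity must be >= 0")
  if (theta < 0) stop_domain("theta must be >= 0")
  structure(list(capacity = capacity, theta = theta, dedup = isTRUE(dedup),
                 keys = character(0), items = list()),
            class = "wm_queue")
}

#' @export
print.wm_queue <- function(x, ...) {
  cat(sprintf("WM queue: %d/%s items pending, theta = %g, %s duplicates\n",
              length(x$items), format(x$capacity), x$theta,
              if (x$dedup) "replaces" else "keeps"))
  invisible(x)
}

#' Offer an update to the working-memory queue
#'
#' @param queue A [wm_queue()].
#' @param item A list identifying the update; must contain `goal` (sub-goal
#'   index), `state` (state id) and `action` (action index), plus anything
#'   the caller wants to carry.
#' @param increment Proposed value change.
#' @return A list with the updated `queue` and logical `accepted`.
#' @export
wm_admit <- function(queue, item, increment) {
  if (abs(increment) <= queue$theta)
    return(list(queue = queue, accepted = FALSE))
  key <- paste(item$goal, item$state, item$action, sep = ":")
  if (queue$dedup) {
    hit <- match(key, queue$keys)
    if (!is.na(hit)) {
      queue$items[[hit]]$increment <- increment
      return(list(queue = queue, accepted = TRUE))
    }
  }
  if (length(queue$items) >= queue$capacity)
    return(list(queue = queue, accepted = FALSE))
  item$increment <- increment
  queue$items <- c(queue$items, list(item))
  queue$keys <- c(queue$keys, key)
  list(queue = queue, accepted = TRUE)
}

#' Flush the working-memory queue into long-term memory
#'
#' Applies pending increments to the q-tables in queue order and empties
#' the queue. Only here does the value function change.
#'
#' @param queue A [wm_queue()].
#' @param qtables List of `q_table`s, one per sub-goal.
#' @return A list with updated `qtables` and the emptied `queue`.
#' @export
flush_to_longterm <- function(queue, qtables) {
  for (it in queue$items) {
    qtables[[it$goal]][it$state, it$action] <-
      qtables[[it$goal]][it$state, it$action] + it$increment
  }
  queue$items <- list()
  queue$keys <- character(0)
  list(qtables = qtables, queue = queue)
}

# greedy action toward the cued target, among distance-reducing actions in
# N > E > S > W priority; used by the teacher policy
teacher_action <- function(task, s) {
  dx <- task$target[1] - s[1]
  dy <- task$target[2] - s[2]
  cand <- character(0)
  if (dy > 0) cand <- c(cand, "N")
  if (dx > 0) cand <- c(cand, "E")
  if (dy < 0) cand <- c(cand, "S")
  if (dx < 0) cand <- c(cand, "W")
  # prefer the axis with more remaining distance, fixed priority on ties
  if (length(cand) == 2L) {
    if (abs(dx) > abs(dy)) cand <- cand[c(grep("[EW]", cand), grep("[NS]", cand))]
  }
  cand[1]
}

#' Run one training trial through the working-memory pipeline
#'
#' For each sub-goal in sequence order, a behaviour policy generates one
#' episode from the start cell until the target is reached or the task step
#' cap is hit. Every transition is proposed as a Q-learning update and
#' offered to the working-memory queue; the queue is flushed to the
#' q-tables once at the end of the trial, so the value function is frozen
#' within a trial.
#'
#' Two behaviour policies are available. `"teacher"` models the cued
#' demonstration: it moves greedily toward the cued target cell, taking a
#' uniformly random action with probability `p_err` per step.
#' `"egreedy"` acts greedily on the agent's own (frozen) q-table with
#' probability `1 - p_err` and randomly otherwise; together with the
#' uniform optimistic initialisation this makes the agent systematically
#' try untested actions, which is what drives unhelpful action values
#' below the optimal ones and lets greedy recall emerge.
#'
#' @param tasks List of [grid_task()]s, one per sub-goal, in sequence order.
#' @param qtables List of `q_table`s matching `tasks`.
#' @param queue A [wm_queue()].
#' @param p_err Random-action probability per step, in `[0, 1)`.
#' @param alpha Learning rate passed to [propose_update()].
#' @param policy `"teacher"` (cued demonstration) or `"egreedy"`.
#' @param record Keep per-transition transcripts (default `TRUE`; turn off
#'   in long sweeps).
#' @param seed Optional seed for the policy's random actions.
#' @return List with updated `qtables`, the (emptied) `queue`, `n_admitted`,
#'   and `transcripts` (one data.frame of transitions per sub-goal, or
#'   `NULL` when `record = FALSE`).
#' @export
run_training_trial <- function(tasks, qtables, queue, p_err = 0.1,
                               alpha = 1, policy = c("teacher", "egreedy"),
                               record = TRUE, seed = NULL) {
  if (p_err < 0 || p_err >= 1) stop_domain("p_err must be in [0, 1)")
  policy <- match.arg(policy)
  with_seed(seed, {
    n_admitted <- 0L
    transcripts <- if (record) vector("list", length(tasks)) else NULL
    for (g in seq_along(tasks)) {
      task <- tasks[[g]]
      q <- qtables[[g]] # frozen during the trial
      s <- task$start
      steps <- 0L
      rows <- if (record) list() else NULL
      repeat {
        a <- if (p_err > 0 && stats::runif(1) < p_err)
          ACTIONS[sample.int(4L, 1L)]
        else if (policy == "teacher") teacher_action(task, s)
        else ACTIONS[which.max(q[state_id(task, s), ])]
        tr <- env_step(task, s, a)
        inc <- propose_update(q, task, tr, alpha)
        adm <- wm_admit(queue,
                        list(goal = g, state = state_id(task, tr$s),
                             action = match(tr$a, ACTIONS)),
                        inc)
        queue <- adm$queue
        if (adm$accepted) n_admitted <- n_admitted + 1L
        if (record) rows[[length(rows) + 1L]] <- data.frame(
          goal = g, step = steps + 1L,
          x = tr$s[1], y = tr$s[2], action = tr$a, reward = tr$r,
          x_next = tr$s_next[1], y_next = tr$s_next[2],
          terminal = tr$terminal, increment = inc, admitted = adm$accepted)
        s <- tr$s_next
        steps <- steps + 1L
        if (tr$terminal || steps >= task$T) break
      }
      if (record) transcripts[[g]] <- do.call(rbind, rows)
    }
    fl <- flush_to_longterm(queue, qtables)
    list(qtables = fl$qtables, queue = fl$queue,
         n_admitted = n_admitted, transcripts = transcripts)
  })
}

#' Greedy recall of the sequence from long-term memory
#'
#' For each sub-goal in order, follows the greedy policy (ties broken by
#' fixed action priority N > E > S > W) from the start cell. A sub-goal is
#' recalled if its target is reached within `budget` steps; recall stops at
#' the first failure, so CR counts consecutively recalled sub-goals from
#' the beginning.
#'
#' @param tasks List of [grid_task()]s in sequence order.
#' @param qtables Matching list of `q_table`s.
#' @param budget Step budget per sub-goal (>= 1); default each task's cap.
#' @return List with `CR` (items) and `steps` (steps used per recalled
#'   sub-goal).
#' @export
run_test_trial <- function(tasks, qtables, budget = NULL) {
  CR <- 0L
  steps_used <- integer(0)
  for (g in seq_along(tasks)) {
    task <- tasks[[g]]
    b <- if (is.null(budget)) task$T else budget
    if (b < 1) stop_domain("budget must be >= 1")
    s <- task$start
    reached <- FALSE
    for (k in seq_len(b)) {
      a <- ACTIONS[which.max(qtables[[g]][state_id(task, s), ])]
      tr <- env_step(task, s, a)
      s <- tr$s_next
      if (tr$terminal) { reached <- TRUE; steps_used <- c(steps_used, k); break }
    }
    if (!reached) break
    CR <- CR + 1L
  }
  list(CR = CR, steps = steps_used)
}

#' Build compass sub-goal grid tasks from a direction sequence
#'
#' Places the start at the grid centre and each sub-goal target `distance`
#' cells away along its compass direction (diagonals offset by `distance`
#' on both axes).
#'
#' @param tokens Character vector of direction tokens
#'   (N, NE, E, SE, S, SW, W, NW).
#' @param width,height Grid dimensions, default 5 x 5.
#' @param distance Cell offset of targets from the centre, default 2.
#' @return List of [grid_task()]s in sequence order.
#' @export
tasks_from_sequence <- function(tokens, width = 5, height = 5, distance = 2) {
  centre <- c((width + 1L) %/% 2L, (height + 1L) %/% 2L)
  offs <- list(N = c(0, 1), NE = c(1, 1), E = c(1, 0), SE = c(1, -1),
               S = c(0, -1), SW = c(-1, -1), W = c(-1, 0), NW = c(-1, 1))
  lapply(tokens, function(tok) {
    if (!tok %in% names(offs)) stop_domain("unknown direction token: ", tok)
    grid_task(width, height, centre,
              centre + distance * offs[[tok]])
  })
}

#' Simulate a whole alternating training/test experiment for one agent
#'
#' Alternates [run_training_trial()] and [run_test_trial()] `n_trials`
#' times and records per-trial correct recall (CR).
#'
#' @param tasks List of [grid_task()]s in sequence order.
#' @param capacity Working-memory queue capacity (items; 0 disables
#'   learning, `Inf` removes the limit).
#' @param n_trials Number of training/test repetitions.
#' @param theta Significance threshold, see [wm_queue()].
#' @param alpha Learning rate.
#' @param p_err Random-action probability of the behaviour policy.
#' @param budget Step budget per sub-goal at test; default each task's cap.
#' @param dedup Queue duplicate handling, see [wm_queue()].
#' @param policy Behaviour policy during training, see
#'   [run_training_trial()]; default `"egreedy"` (recall-driven
#'   exploration), the mode under which iterative sub-goal learning
#'   emerges.
#' @param stop_at_completion Stop simulating once a test trial recalls the
#'   whole sequence (default `FALSE`); the session then has fewer than
#'   `n_trials` rows.
#' @param seed Optional seed.
#' @return An `rl_session`: data.frame with columns `trial`, `CR`,
#'   `n_admitted`, plus attributes `trials_to_complete` (first trial whose
#'   CR equals the sequence length, `NA` if never) and `n_goals`.
#' @export
simulate_rl_experiment <- function(tasks, capacity, n_trials,
                                   theta = 1e-6, alpha = 1, p_err = 0.1,
                                   budget = NULL, dedup = TRUE,
                                   policy = "egreedy",
                                   stop_at_completion = FALSE, seed = NULL) {
  with_seed(seed, {
    qtables <- lapply(tasks, new_q_table)
    queue <- wm_queue(capacity, theta = theta, dedup = dedup)
    CR <- integer(n_trials)
    adm <- integer(n_trials)
    n_run <- 0L
    for (t in seq_len(n_trials)) {
      res <- run_training_trial(tasks, qtables, queue,
                                p_err = p_err, alpha = alpha,
                                policy = policy, record = FALSE)
      qtables <- res$qtables
      queue <- res$queue
      adm[t] <- res$n_admitted
      CR[t] <- run_test_trial(tasks, qtables, budget)$CR
      n_run <- t
      if (stop_at_completion && CR[t] == length(tasks)) break
    }
    CR <- CR[seq_len(n_run)]
    adm <- adm[seq_len(n_run)]
    out <- data.frame(trial = seq_len(n_run), CR = CR, n_admitted = adm)
    ttc <- which(CR == length(tasks))[1]
    attr(out, "trials_to_complete") <- if (length(ttc) && !is.na(ttc))
      as.integer(ttc) else NA_integer_
    attr(out, "n_goals") <- length(tasks)
    attr(out, "qtables") <- qtables
    class(out) <- c("rl_session", "data.frame")
    out
  })
}

#' @export
print.rl_session <- function(x, ...) {
  ttc <- attr(x, "trials_to_complete")
  cat(sprintf("RL session: %d sub-goals, %d trials, complete at trial %s\n",
              attr(x, "n_goals"), nrow(x),
              if (is.na(ttc)) "never" else ttc))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Serialize agent q-tables to JSON
#'
#' @param qtables List of `q_table`s.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_agent_state <- function(qtables, path) {
  out <- lapply(qtables, function(q) {
    m <- unclass(q)
    list(values = as.vector(m), nrow = nrow(m), actions = colnames(m))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore agent q-tables from JSON
#'
#' @param path File written by [write_agent_state()].
#' @return List of `q_table`s.
#' @export
read_agent_state <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(el) {
    q <- matrix(el$values, nrow = el$nrow, ncol = length(el$actions),
                dimnames = list(NULL, el$actions))
    class(q) <- c("q_table", class(q))
    q
  })
}
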