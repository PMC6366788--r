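# Independent brute-force oracles used to cross-check the model code.

# movement time recomputed through natural logs, independent of log2()
oracle_mt <- function(A, W, a, b, c) a + b * log(A) / log(2) + c * log(W) / log(2)

# largest prefix of loads[start..n] whose sum fits in C, by enumeration
oracle_max_chunk <- function(loads, start, C) {
  n <- length(loads)
  best <- 0L
  for (m in seq_len(n - start + 1L)) {
    if (sum(loads[start:(start + m - 1L)]) <= C) best <- m else break
  }
  best
}

# full learning curve by repeated enumeration (no forced progress)
oracle_learning_curve <- function(loads, C, max_iters = 100) {
  n <- length(loads)
  frontier <- 0L
  rec <- integer(0)
  for (t in seq_len(max_iters)) {
    if (frontier >= n) break
    m <- oracle_max_chunk(loads, frontier + 1L, C)
    if (m == 0L) m <- 1L # mirrors force_progress
    frontier <- frontier + m
    rec <- c(rec, frontier)
  }
  rec
}

# optimal q-table for a grid task, by direct distance computation:
# q*(s, a) = -1 + V*(s') = -(1 + Manhattan distance from the successor of
# (s, a) to the target); actions from the target cell are never queried
oracle_optimal_q <- function(task) {
  q <- new_q_table(task)
  for (x in seq_len(task$width)) for (y in seq_len(task$height)) {
    if (all(c(x, y) == task$target)) next
    for (a in c("N", "E", "S", "W")) {
      tr <- env_step(task, c(x, y), a)
      d_next <- sum(abs(tr$s_next - task$target))
      sid <- (y - 1L) * task$width + x
      q[sid, a] <- -(1 + d_next)
    }
  }
  q
}

# a session table with hand-constructed CR values, for block statistics
make_session_table <- function(CR_by_participant) {
  do.call(rbind, lapply(names(CR_by_participant), function(id) {
    cr <- CR_by_participant[[id]]
    data.frame(participant_id = id, trial_index = seq_along(cr), CR = cr)
  }))
}
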