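task5 <- function() grid_task(5, 5, start = c(3, 3), target = c(5, 3))

test_that("grid steps are deterministic with wall bounce-back", {
  tk <- task5()
  # west edge, action W: agent stays put, still pays -1
  tr <- env_step(tk, c(1, 3), "W")
  expect_equal(tr$s_next, c(1, 3))
  expect_equal(tr$r, -1)
  expect_false(tr$terminal)
  # interior move
  tr2 <- env_step(tk, c(3, 3), "N")
  expect_equal(tr2$s_next, c(3, 4))
  # stepping onto the target terminates
  tr3 <- env_step(tk, c(4, 3), "E")
  expect_true(tr3$terminal)
  expect_equal(tr3$s_next, c(5, 3))
  expect_error(env_step(tk, c(0, 3), "N"), "outside grid")
})

test_that("grid task construction validates its geometry", {
  expect_error(grid_task(5, 5, c(3, 3), c(3, 3)), "differ")
  expect_error(grid_task(5, 5, c(3, 3), c(6, 3)), "inside")
  expect_error(grid_task(5, 5, c(1, 1), c(5, 5), T = 3), "Manhattan")
})

test_that("proposed updates are correct and do not touch the table", {
  tk <- task5()
  q0 <- new_q_table(tk)
  # all-zero table, terminal transition, alpha 1 -> increment -1
  tr <- env_step(tk, c(4, 3), "E")
  expect_equal(propose_update(q0, tk, tr, alpha = 1), -1)
  # non-terminal, alpha 0.5 -> 0.5 * (-1 + 0 - 0)
  tr2 <- env_step(tk, c(3, 3), "N")
  expect_equal(propose_update(q0, tk, tr2, alpha = 0.5), -0.5)
  expect_true(all(q0 == 0)) # proposals never mutate
  # converged table: every on-policy increment is zero
  qstar <- oracle_optimal_q(tk)
  for (s in list(c(3, 3), c(4, 3), c(2, 5))) {
    a <- c("N", "E", "S", "W")[which.max(qstar[(s[2] - 1) * 5 + s[1], ])]
    trc <- env_step(tk, s, a)
    expect_equal(propose_update(qstar, tk, trc, alpha = 1), 0)
  }
})

test_that("the queue admits by free space and significance", {
  q <- wm_queue(capacity = 2, theta = 0)
  # zero increment is not significant even at theta = 0 (strict)
  r <- wm_admit(q, list(goal = 1, state = 1, action = 1), 0)
  expect_false(r$accepted)
  # empty queue, significant increment -> accepted
  r <- wm_admit(q, list(goal = 1, state = 1, action = 1), -1)
  expect_true(r$accepted)
  expect_length(r$queue$items, 1)
  r <- wm_admit(r$queue, list(goal = 1, state = 2, action = 1), -1)
  expect_true(r$accepted)
  # full queue rejects a new pair
  r2 <- wm_admit(r$queue, list(goal = 1, state = 3, action = 1), -1)
  expect_false(r2$accepted)
  expect_length(r2$queue$items, 2)
  # ... but a repeated pair replaces its pending update in place
  r3 <- wm_admit(r$queue, list(goal = 1, state = 1, action = 1), -0.25)
  expect_true(r3$accepted)
  expect_length(r3$queue$items, 2)
  expect_equal(r3$queue$items[[1]]$increment, -0.25)
  # sub-threshold magnitudes are rejected outright
  q2 <- wm_queue(capacity = 10, theta = 0.5)
  expect_false(wm_admit(q2, list(goal = 1, state = 1, action = 1), 0.5)$accepted)
  expect_true(wm_admit(q2, list(goal = 1, state = 1, action = 1), 0.6)$accepted)
})

test_that("flush applies queued increments in order and empties the queue", {
  tk <- task5()
  qt <- list(new_q_table(tk))
  # empty queue leaves the table unchanged
  fl <- flush_to_longterm(wm_queue(4), qt)
  expect_equal(fl$qtables, qt)
  # one increment
  q <- wm_queue(4, theta = 0)
  q <- wm_admit(q, list(goal = 1, state = 13, action = 2), -1)$queue
  fl <- flush_to_longterm(q, qt)
  expect_equal(unname(fl$qtables[[1]][13, 2]), -1)
  expect_length(fl$queue$items, 0)
  # duplicates kept (dedup off) apply sequentially: hand-applied two-step
  q2 <- wm_queue(4, theta = 0, dedup = FALSE)
  q2 <- wm_admit(q2, list(goal = 1, state = 13, action = 2), -1)$queue
  q2 <- wm_admit(q2, list(goal = 1, state = 13, action = 2), -0.5)$queue
  expect_length(q2$items, 2)
  fl2 <- flush_to_longterm(q2, qt)
  expect_equal(unname(fl2$qtables[[1]][13, 2]), 0 + (-1) + (-0.5))
})

test_that("teacher demonstrations take shortest paths when error-free", {
  tasks <- tasks_from_sequence(c("E", "NE"), width = 5, height = 5,
                               distance = 2)
  qt <- lapply(tasks, new_q_table)
  res <- run_training_trial(tasks, qt, wm_queue(Inf, theta = 0),
                            p_err = 0, policy = "teacher", seed = 1)
  for (g in 1:2) {
    d <- tasks[[g]]$dist
    expect_equal(nrow(res$transcripts[[g]]), d) # exactly d steps
    expect_equal(sum(res$transcripts[[g]]$reward), -d) # return -d
    expect_true(res$transcripts[[g]]$terminal[d])
  }
})

test_that("zero working-memory capacity means no learning at all", {
  tasks <- tasks_from_sequence(c("E", "S"))
  qt <- lapply(tasks, new_q_table)
  res <- run_training_trial(tasks, qt, wm_queue(0, theta = 0),
                            p_err = 0.3, seed = 2)
  expect_equal(res$n_admitted, 0L)
  expect_equal(res$qtables, qt) # tables identical before and after
})

test_that("seeded training transcripts are reproducible", {
  tasks <- tasks_from_sequence(c("E", "S"))
  qt <- lapply(tasks, new_q_table)
  r1 <- run_training_trial(tasks, qt, wm_queue(Inf), p_err = 0.5, seed = 42)
  r2 <- run_training_trial(tasks, qt, wm_queue(Inf), p_err = 0.5, seed = 42)
  expect_identical(r1$transcripts, r2$transcripts)
  expect_identical(r1$qtables, r2$qtables)
})

test_that("greedy recall counts consecutive sub-goals from the start", {
  tasks <- tasks_from_sequence(c("E", "S", "W", "NE"))
  # fully converged tables -> CR = sequence length, optimal step counts
  qstar <- lapply(tasks, oracle_optimal_q)
  res <- run_test_trial(tasks, qstar)
  expect_equal(res$CR, 4L)
  expect_equal(res$steps, vapply(tasks, function(t) t$dist, integer(1)))
  # naive tables: fixed N > E > S > W tie-break runs into the top wall and
  # never reaches an eastern target within a tight budget
  qnaive <- lapply(tasks, new_q_table)
  expect_equal(run_test_trial(tasks, qnaive, budget = 4)$CR, 0L)
  # first k converged, rest naive -> CR = k
  for (k in 0:3) {
    mixed <- c(qstar[seq_len(k)], qnaive[seq(k + 1, 4)])
    expect_equal(run_test_trial(tasks, mixed, budget = 4)$CR, as.integer(k))
  }
})

test_that("the value function is frozen between flushes", {
  tasks <- tasks_from_sequence("E")
  qt <- lapply(tasks, new_q_table)
  snap <- qt
  queue <- wm_queue(Inf, theta = 0)
  # offer transitions without flushing: table must not move
  s <- tasks[[1]]$start
  for (i in 1:5) {
    tr <- env_step(tasks[[1]], s, "E")
    inc <- propose_update(qt[[1]], tasks[[1]], tr)
    queue <- wm_admit(queue, list(goal = 1, state = 1, action = 2), inc)$queue
    s <- tr$s_next
    if (tr$terminal) s <- tasks[[1]]$start
  }
  expect_identical(qt, snap)
  fl <- flush_to_longterm(queue, qt)
  expect_false(identical(fl$qtables, snap))
})

test_that("learned sub-goals stop competing for working memory", {
  tasks <- tasks_from_sequence(c("E", "S"))
  qstar <- lapply(tasks, oracle_optimal_q)
  # a converged goal generates only zero increments: nothing admitted
  res <- run_training_trial(tasks, qstar, wm_queue(Inf, theta = 1e-6),
                            p_err = 0, policy = "teacher", seed = 3)
  expect_equal(res$n_admitted, 0L)
  expect_equal(res$qtables, qstar)
})

test_that("experiment simulation is seed-reproducible and capacity-sensitive", {
  tasks <- tasks_from_sequence(c("E", "S", "W", "N"),
                               width = 3, height = 3, distance = 1)
  s1 <- simulate_rl_experiment(tasks, capacity = 4, n_trials = 30, seed = 9)
  s2 <- simulate_rl_experiment(tasks, capacity = 4, n_trials = 30, seed = 9)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # unlimited capacity learns the whole sequence
  sInf <- simulate_rl_experiment(tasks, capacity = Inf, n_trials = 60,
                                 p_err = 0.2, seed = 1)
  expect_equal(max(sInf$CR), 4L)
  expect_false(is.na(attr(sInf, "trials_to_complete")))
  # zero capacity never does
  s0 <- simulate_rl_experiment(tasks, capacity = 0, n_trials = 20,
                               p_err = 0.2, seed = 1)
  expect_equal(max(s0$CR), 0L)
})

test_that("agent state round-trips through JSON", {
  tasks <- tasks_from_sequence(c("E", "NW"))
  sess <- simulate_rl_experiment(tasks, capacity = Inf, n_trials = 10,
                                 seed = 4)
  qt <- attr(sess, "qtables")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_agent_state(qt, path)
  back <- read_agent_state(path)
  expect_equal(length(back), 2)
  for (g in 1:2) expect_equal(unclass(back[[g]]), unclass(qt[[g]]))
})
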