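test_that("cohort sampling is seeded and ordered across groups", {
  cfg <- cohort_config(n_younger = 5, n_older = 5, cv = 0.1, seed = 7)
  c1 <- sample_cohort(cfg)
  c2 <- sample_cohort(cfg)
  expect_identical(c1, c2)
  expect_length(c1, 10)
  # zero variance -> all profiles equal their group means
  c0 <- sample_cohort(cohort_config(3, 3, cv = 0, seed = 1))
  gm_y <- default_group_params("younger")
  gm_o <- default_group_params("older")
  expect_equal(c0[[1]]$C, gm_y$C)
  expect_equal(c0[[4]]$C, gm_o$C)
  expect_equal(c0[[1]]$b, gm_y$b)
  # defaults encode the age contrast: smaller capacity, slower noisier
  # movements in the older group
  expect_lt(gm_o$C, gm_y$C)
  expect_gt(gm_o$a, gm_y$a)
  expect_gt(gm_o$b, gm_y$b)
  expect_gt(abs(gm_o$c), abs(gm_y$c))
  expect_gt(gm_o$lambda, gm_y$lambda)
  expect_error(cohort_config(0, 0), "at least one")
})

test_that("sessions are seed-deterministic", {
  spec <- experiment_spec("exp2")
  p <- participant_profile("y1", "younger")
  s1 <- generate_session(p, spec, seed = 3, traces = FALSE)
  s2 <- generate_session(p, spec, seed = 3, traces = FALSE)
  expect_identical(s1$outcomes, s2$outcomes)
  expect_identical(s1$events, s2$events)
  # the shared sequence is identical across participants
  p2 <- participant_profile("o1", "older")
  s3 <- generate_session(p2, spec, seed = 99, traces = FALSE)
  expect_identical(s1$sequence, s3$sequence)
})

test_that("corrective submovements lengthen the path, jitter-free baseline", {
  spec <- experiment_spec("exp2")
  base <- default_group_params("younger")
  base$sigma <- 0; base$recall_sd <- 0
  p0 <- participant_profile("y0", "younger", modifyList(base, list(lambda = 0)))
  p2 <- participant_profile("y2", "younger", modifyList(base, list(lambda = 2)))
  s0 <- generate_session(p0, spec, seed = 6, traces = TRUE)
  s2 <- generate_session(p2, spec, seed = 6, traces = TRUE)
  tr_ids <- unique(s0$outcomes$trial_index[s0$outcomes$trial_type == "training"])
  for (id in tr_ids) {
    pl0 <- compute_PL(s0$traces[s0$traces$trial_id == id, ])
    pl2 <- compute_PL(s2$traces[s2$traces$trial_id == id, ])
    expect_gt(pl2, pl0) # corrections add arc length in every trial
  }
})

test_that("noise-free sessions reproduce the movement model exactly", {
  spec <- experiment_spec("exp2")
  p <- participant_profile("y1", "younger")
  s <- generate_session(p, spec, seed = 5, traces = TRUE, noise = FALSE)
  # PL equals the exact straight out-and-back total
  tr1 <- s$traces[s$traces$trial_id == 1, ]
  expect_equal(compute_PL(tr1), 2 * spec$length * spec$layout$distance,
               tolerance = 1e-9)
  # MT_r recovers the movement-time law prediction to machine precision
  ev <- s$events[s$events$trial_id == 2, ]
  expect_equal(compute_MT_r(ev), s$movement_time, tolerance = 1e-12)
  # test-trial traces end with a terminating centre dwell
  tt <- s$traces[s$traces$trial_id == 2, ]
  expect_lt(detect_termination(tt, spec$layout), nrow(tt))
})

test_that("sessions round-trip losslessly through their file formats", {
  spec <- experiment_spec("exp2")
  p <- participant_profile("o1", "older")
  s <- generate_session(p, spec, seed = 12, traces = TRUE)
  d1 <- file.path(tempdir(), "wmseq-s1")
  d2 <- file.path(tempdir(), "wmseq-s2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_session(s, d1)
  back <- read_session(d1)
  expect_identical(back$sequence, s$sequence)
  expect_equal(back$outcomes, s$outcomes)
  expect_equal(back$events, s$events)
  expect_equal(back$profile$C, s$profile$C)
  # write -> read -> write gives byte-identical manifests
  write_session(back, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  expect_error(read_session(tempfile()), "missing session")
})

test_that("condition contrasts hold under the default calibration", {
  spec <- experiment_spec("exp2")
  cfg <- cohort_config(4, 4, cv = 0.05, seed = 20)
  tab <- simulate_cohort(cfg, spec, hands = c("preferred", "nonpreferred"))
  tst <- tab[tab$trial_type == "test", ]
  m <- function(...) {
    sub <- tst
    sel <- list(...)
    for (nm in names(sel)) sub <- sub[sub[[nm]] == sel[[nm]], ]
    mean(sub$CR)
  }
  # late recall beats early recall
  early <- mean(tst$CR[tst$repetition <= 3])
  late <- mean(tst$CR[tst$repetition >= 8])
  expect_gt(late, early)
  # younger beats older, preferred beats non-preferred
  expect_gt(m(group = "younger"), m(group = "older"))
  expect_gt(m(group = "younger", hand = "preferred"),
            m(group = "younger", hand = "nonpreferred"))
})

test_that("sideways orientation slows and lengthens training movements", {
  spec <- experiment_spec("exp3")
  p <- participant_profile("y1", "younger")
  sr <- generate_session(p, spec, orientation = "regular", seed = 14,
                         traces = TRUE)
  ss <- generate_session(p, spec, orientation = "sideways", seed = 14,
                         traces = TRUE)
  tr_r <- sr$outcomes[sr$outcomes$trial_type == "training", ]
  tr_s <- ss$outcomes[ss$outcomes$trial_type == "training", ]
  expect_gt(mean(tr_s$MT_t), mean(tr_r$MT_t))
  expect_gt(mean(tr_s$PL), mean(tr_r$PL))
  # and recall suffers
  expect_gt(mean(sr$outcomes$CR, na.rm = TRUE),
            mean(ss$outcomes$CR, na.rm = TRUE))
})

test_that("the RL engine can drive session generation", {
  spec <- experiment_spec("exp2")
  p <- participant_profile("y1", "younger")
  attr(p, "engine") <- "wm_qlearning"
  s <- generate_session(p, spec, seed = 2, traces = FALSE)
  cr <- s$outcomes$CR[s$outcomes$trial_type == "test"]
  expect_length(cr, 10)
  expect_true(all(cr >= 0 & cr <= 16))
})

test_that("average increments reproduce per-trial chunking tables", {
  spec <- experiment_spec("exp2")
  cfg <- cohort_config(3, 3, cv = 0, seed = 2)
  tab <- simulate_cohort(cfg, spec, noise = FALSE)
  inc <- average_increments(tab)
  y <- inc[inc$group == "younger", ]
  o <- inc[inc$group == "older", ]
  expect_equal(nrow(y), 10)
  # deterministic defaults: younger store four items per early trial,
  # older one
  expect_equal(y$mean_increment[1:3], c(4, 4, 4))
  expect_equal(o$mean_increment[1:3], c(1, 1, 1))
})
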