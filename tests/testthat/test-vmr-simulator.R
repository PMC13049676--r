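test_that("the task schedule partitions the session into the four blocks", {
  sch <- task_schedule()
  expect_equal(sch$n_trials, 550L)
  expect_equal(as.vector(table(sch$blocks$block)), c(100L, 200L, 200L, 50L))
  expect_error(task_schedule(baseline = 1:101), "partition")
  expect_error(task_schedule(slow_threshold_mm_s = 500), "below")
})

test_that("the point system reproduces the published mapping", {
  # reward bins: hit, <10, <20, <30, >=30
  expect_identical(assign_points(0, TRUE, "ok", "reward"), 4L)
  expect_identical(assign_points(c(5, 15, 25, 35), FALSE, "ok", "reward"),
                   c(3L, 2L, 1L, 0L))
  # punishment bins are the mirrored scale
  expect_identical(assign_points(0, TRUE, "ok", "punishment"), 0L)
  expect_identical(assign_points(c(5, 15, 25, 35), FALSE, "ok", "punishment"),
                   c(-1L, -2L, -3L, -4L))
  # slow / fast force the worst bin regardless of accuracy
  expect_identical(assign_points(5, FALSE, "fast", "punishment"), -4L)
  expect_identical(assign_points(0, TRUE, "slow", "reward"), 0L)
  expect_error(assign_points(5, FALSE, "ok", "neutral"), "condition")
  expect_error(assign_points(-1, FALSE, "ok", "reward"), "non-negative")
})

test_that("outcome classification marks only the best bin as success", {
  expect_equal(as.character(classify_outcome(c(4, 3, 0), "reward")),
               c("success", "failure", "failure"))
  expect_equal(as.character(classify_outcome(c(0, -1, -4), "punishment")),
               c("success", "failure", "failure"))
  expect_error(classify_outcome(5, "reward"), "out of range")
})

test_that("an error-free performer earns the 800-point maximum", {
  pr <- perfect_session(condition = "reward")
  expect_identical(tail(pr$cum_points, 1), 800L)
  # 200 adaptation trials at 4 points each, no clipping needed
  expect_identical(sum(pr$points), 800L)
  pp <- perfect_session(condition = "punishment")
  expect_identical(tail(pp$cum_points, 1), 800L)  # endowment kept intact
})

test_that("the state-space learner has the expected boundary behavior", {
  sch <- task_schedule()
  # no learning, no noise: flat at zero, zero points
  tr0 <- simulate_participant(
    sch, adaptation_params(learn_rate = 0, motor_noise_sd_deg = 0, seed = 1),
    "reward")
  expect_true(all(tr0$theta_deg == 0))
  expect_identical(tail(tr0$cum_points, 1), 0L)
  # one-shot learner: full compensation from trial 102 onward, 4 points each
  tr1 <- simulate_participant(
    sch, adaptation_params(learn_rate = 1, retention_rate_adapt = 1,
                           motor_noise_sd_deg = 0, seed = 1),
    "reward")
  expect_equal(tr1$theta_deg[102:300], rep(30, 199))
  expect_true(all(tr1$points[102:300] == 4L))
  # perfect retention keeps the adapted state through no-vision
  tr2 <- simulate_participant(
    sch, adaptation_params(learn_rate = 1, retention_rate_adapt = 1,
                           retention_rate_no_vision = 1,
                           motor_noise_sd_deg = 0, seed = 1),
    "reward")
  expect_equal(retention_amount(tr2), 100)
})

test_that("simulation is deterministic given the seed and points accumulate correctly", {
  sch <- task_schedule()
  p <- adaptation_params(seed = 42)
  a <- simulate_participant(sch, p, "punishment")
  b <- simulate_participant(sch, p, "punishment")
  expect_identical(a, b)
  # cum_points equals the clipped running sum of per-trial points
  run <- 800L
  for (i in seq_len(nrow(a))) {
    if (a$block[i] == "adaptation") {
      run <- min(max(run + a$points[i], 0L), 800L)
    }
    expect_identical(a$cum_points[i], run)
  }
  # points are awarded only during the adaptation block
  expect_true(all(a$points[a$block != "adaptation"] == 0L))
})

test_that("retention amount is monotone in the no-vision retention rate", {
  sch <- task_schedule()
  rates <- c(0.9, 0.95, 0.98, 0.995, 1)
  rets <- vapply(rates, function(r) {
    p <- adaptation_params(retention_rate_no_vision = r, seed = 7)
    retention_amount(simulate_participant(sch, p, "reward"))
  }, numeric(1))
  expect_true(all(diff(rets) > 0))
})

test_that("the cohort generator plants a reward-specific feature-retention link", {
  coh <- simulate_cohort(16, cohort_effect(), seed = 3, keep_trials = FALSE)
  expect_equal(nrow(coh), 32L)
  expect_equal(sum(coh$condition == "reward"), 16L)
  # zero planted slope: reward-group correlation is near zero on average
  rs <- vapply(1:6, function(s) {
    c0 <- simulate_cohort(16, cohort_effect(slope = 0), seed = 100 + s,
                          keep_trials = FALSE)
    r <- c0[c0$condition == "reward", ]
    cor(r$gt_alpha_erd_late, r$retention_pct)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.25)
  expect_warning(cohort_effect(alpha_erd_sd = 0), "Degenerate")
})

test_that("with low noise the reward-group regression recovers the planted slope", {
  slopes <- vapply(1:10, function(s) {
    coh <- simulate_cohort(
      16, cohort_effect(slope = 0.34, retention_noise_sd = 2,
                        erd_noise_sd = 0),
      seed = 200 + s, keep_trials = FALSE)
    r <- coh[coh$condition == "reward", ]
    unname(coef(lm(retention_pct ~ gt_alpha_erd_late, data = r))[2])
  }, numeric(1))
  expect_equal(mean(slopes), 0.34, tolerance = 0.1)
})
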