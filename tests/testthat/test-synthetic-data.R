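test_that("the default session reproduces the lateral-masking protocol", {
  d <- session_design()
  expect_equal(d$contrast_levels,
               c(0.0075, 0.015, 0.0225, 0.03, 0.045, 0.06, 0.09))
  expect_equal(trials_per_block(d), 140)
  expect_equal(n_blocks(d), 7)
  expect_equal(trials_per_observer(d), 980)
  expect_setequal(d$conditions,
                  c("1", "2", "3", "4", "6", "12", "baseline"))
})

test_that("session design rejects malformed inputs", {
  expect_error(session_design(contrast_levels = c(0.1, 0.05)),
               "strictly increasing")
  expect_error(session_design(contrast_levels = c(0, 0.5)), "in \\(0, 1\\]")
  expect_error(session_design(contrast_levels = c(0.1, 1.2)), "in \\(0, 1\\]")
  expect_error(session_design(reps_per_level = 0), "integer >= 1")
  expect_error(session_design(flanker_distances = c(-1, 2)), "positive")
  expect_error(session_design(flanker_distances = numeric(0),
                              include_baseline = FALSE),
               "at least one condition")
})

test_that("zero random-effect covariance gives identical same-group observers", {
  pop <- population_params(beta = c(-0.5, 29, -0.391, 12.313),
                           sigma_re = matrix(0, 2, 2),
                           group_sizes = c(control = 5, migraine_aura = 4))
  obs <- draw_observers(pop, seed = 3)
  ctl <- obs[obs$group == "control", ]
  mig <- obs[obs$group == "migraine_aura", ]
  expect_true(all(ctl$intercept == -0.5) && all(ctl$contrast_slope == 29))
  expect_true(all(mig$intercept == -0.5 - 0.391))
  expect_true(all(mig$contrast_slope == 29 + 12.313))
})

test_that("observer draws follow the stated bivariate-normal generator", {
  n <- 10000
  pop <- population_params(beta = c(-0.5, 29, -0.391, 12.313),
                           sigma_re = diag(c(0.04, 4)),
                           group_sizes = c(control = n, migraine_aura = n))
  obs <- draw_observers(pop, seed = 11)
  ctl <- obs[obs$group == "control", ]
  # SD of a sample SD is approximately sigma / sqrt(2 n)
  expect_lt(abs(sd(ctl$intercept) - 0.2), 3 * 0.2 / sqrt(2 * n))
  expect_lt(abs(sd(ctl$contrast_slope) - 2), 3 * 2 / sqrt(2 * n))
  # group offsets recovered across groups within 3 MC SEs of the mean diff
  slope_diff <- mean(obs$contrast_slope[obs$group == "migraine_aura"]) -
    mean(ctl$contrast_slope)
  expect_lt(abs(slope_diff - 12.313), 3 * 2 * sqrt(2 / n))
  int_diff <- mean(obs$intercept[obs$group == "migraine_aura"]) -
    mean(ctl$intercept)
  expect_lt(abs(int_diff - (-0.391)), 3 * 0.2 * sqrt(2 / n))
})

test_that("draws are reproducible and PSD violations are caught", {
  pop <- population_params(group_sizes = c(control = 4, migraine_aura = 4))
  expect_identical(draw_observers(pop, seed = 5), draw_observers(pop, seed = 5))
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(population_params(sigma_re = bad), "sigma_re.*positive semi")
  expect_error(population_params(sigma_re = matrix(c(1, 0.5, 0, 1), 2, 2)),
               "symmetric")
})

test_that("one condition block has the designed trial count and composition", {
  obs <- list(observer_id = "S1", group = "control",
              intercept = -0.5, contrast_slope = 29)
  blk <- simulate_trials(obs, session_design(), condition = "3", seed = 2)
  expect_equal(nrow(blk), 140)
  expect_equal(unname(table(blk$contrast)), rep(20L, 7),
               ignore_attr = TRUE)
  expect_true(all(blk$correct %in% c(0, 1)))
  expect_true(all(blk$condition == "3"))
  expect_error(simulate_trials(obs, session_design(), condition = "5"),
               "not part of the session design")
  obs$intercept <- Inf
  expect_error(simulate_trials(obs, session_design(), condition = "3"),
               "Non-finite linear predictor")
})

test_that("simulated outcomes follow the probit psychometric function", {
  d <- session_design(reps_per_level = 10000,
                      flanker_distances = numeric(0))
  # chance performance at a flat zero linear predictor
  flat <- simulate_trials(list(observer_id = "S1", group = "control",
                               intercept = 0, contrast_slope = 0),
                          d, "baseline", seed = 4)
  p_hat <- tapply(flat$correct, flat$contrast, mean)
  expect_true(all(abs(p_hat - 0.5) < 3 * sqrt(0.25 / 10000)))
  # convergence of the aggregate proportion to pnorm(eta) per level
  obs <- list(observer_id = "S1", group = "control",
              intercept = -0.5, contrast_slope = 29)
  blk <- simulate_trials(obs, d, "baseline", seed = 5)
  p_true <- pnorm(-0.5 + 29 * d$contrast_levels)
  p_hat <- tapply(blk$correct, blk$contrast, mean)[as.character(d$contrast_levels)]
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_true(all(abs(p_hat - p_true) < 3 * se))
  # saturation
  sat <- simulate_trials(list(observer_id = "S1", group = "control",
                              intercept = 10, contrast_slope = 0),
                         session_design(), "baseline", seed = 6)
  expect_true(all(sat$correct == 1))
})

test_that("the full dataset obeys the design arithmetic and is deterministic", {
  pop1 <- population_params(group_sizes = c(control = 1, migraine_aura = 1))
  one <- simulate_dataset(pop1, session_design(), seed = 9)
  one_obs <- one[one$observer_id == one$observer_id[1], ]
  expect_equal(length(unique(one_obs$condition)), 7)
  expect_equal(nrow(one_obs), 980)

  pop <- population_params(group_sizes = c(control = 3, migraine_aura = 2))
  t1 <- simulate_dataset(pop, session_design(), seed = 77)
  expect_equal(nrow(t1), 5 * 7 * 140)
  counts <- table(t1$observer_id, t1$condition)
  expect_true(all(counts == 140))
  t2 <- simulate_dataset(pop, session_design(), seed = 77)
  expect_identical(t1, t2)
  t3 <- simulate_dataset(pop, session_design(), seed = 78)
  expect_false(identical(t1, t3))
})

test_that("condition effects shift performance only in the named blocks", {
  pop <- population_params(
    beta = c(-0.5, 29, 0, 0), sigma_re = matrix(0, 2, 2),
    group_sizes = c(control = 2, migraine_aura = 2),
    condition_effects = c("1" = 3)
  )
  trials <- simulate_dataset(pop, session_design(reps_per_level = 200),
                             seed = 12)
  p1 <- mean(trials$correct[trials$condition == "1"])
  pb <- mean(trials$correct[trials$condition == "baseline"])
  expect_gt(p1, pb + 0.1)
  expect_error(
    simulate_dataset(
      population_params(condition_effects = c("5" = 1),
                        group_sizes = c(control = 1, migraine_aura = 1)),
      session_design(), seed = 1),
    "not in the design")
})
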