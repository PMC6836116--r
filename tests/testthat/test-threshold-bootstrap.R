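test_that("threshold inversion matches the closed form and the bisection oracle", {
  expect_equal(threshold_75(0, 1, criterion = 0.5), 0)
  expect_equal(threshold_75(0, 1), oracle_qnorm_bisect(0.75),
               tolerance = 1e-6)
  expect_equal(round(threshold_75(0, 1), 6), 0.674490)
  expect_equal(threshold_75(-0.5, 29), (0.67449 + 0.5) / 29,
               tolerance = 1e-4)
  expect_error(threshold_75(0, 0), "threshold undefined")
  expect_warning(threshold_75(0.2, -3), "Negative")
  expect_error(threshold_75(0, 1, criterion = 1), "\\(0, 1\\)")
  expect_error(threshold_75(Inf, 1), "finite")
})

test_that("threshold and psychometric prediction are mutual inverses", {
  grid <- expand.grid(a = c(-1, -0.5, 0, 0.4),
                      b = c(5, 29, 60),
                      crit = c(0.6, 0.75, 0.9))
  th <- threshold_75(grid$a, grid$b, rep(0.75, nrow(grid)))
  for (i in seq_len(nrow(grid))) {
    t_i <- threshold_75(grid$a[i], grid$b[i], grid$crit[i])
    expect_lt(abs(pnorm(grid$a[i] + grid$b[i] * t_i) - grid$crit[i]), 1e-10)
  }
  # and through a fitted model
  trials <- sim_baseline(group_sizes = c(control = 4, migraine_aura = 4),
                         seed = 7)
  fit <- fit_probit_glmm(trials, nAGQ = 3, compute_cov = FALSE)
  th <- group_thresholds(fit)
  for (i in seq_len(nrow(th))) {
    expect_lt(abs(predict_p(fit, th$threshold[i], group = th$group[i]) - 0.75),
              1e-10)
  }
})

test_that("group thresholds read off the fixed effects", {
  trials <- sim_baseline(beta = c(-0.5, 29, -0.391, 12.313),
                         group_sizes = c(control = 5, migraine_aura = 5),
                         seed = 17)
  fit <- fit_probit_glmm(trials, nAGQ = 3, compute_cov = FALSE)
  th <- group_thresholds(fit)
  b <- fit$beta_hat
  expect_equal(th$threshold[th$group == "control"],
               (qnorm(0.75) - b[["(Intercept)"]]) / b[["contrast"]])
  expect_equal(th$threshold[th$group == "migraine_aura"],
               (qnorm(0.75) - b[["(Intercept)"]] - b[["group"]]) /
                 (b[["contrast"]] + b[["group:contrast"]]))
})

test_that("the bootstrap is reproducible and bookkeeps its samples", {
  trials <- sim_baseline(sigma_re = diag(c(0.02, 4)),
                         group_sizes = c(control = 6, migraine_aura = 6),
                         seed = 23)
  fit <- fit_probit_glmm(trials, nAGQ = 1)
  b1 <- bootstrap_threshold_sd(fit, baseline_only_design(), n_samples = 8,
                               seed = 99, nAGQ = 1)
  b2 <- bootstrap_threshold_sd(fit, baseline_only_design(), n_samples = 8,
                               seed = 99, nAGQ = 1)
  expect_identical(b1$thresholds, b2$thresholds)
  expect_identical(b1$sd, b2$sd)
  expect_equal(b1$n_samples + b1$n_dropped, b1$n_requested)
  expect_s3_class(autoplot(b1), "ggplot")
  b3 <- bootstrap_threshold_sd(fit, baseline_only_design(), n_samples = 8,
                               seed = 100, nAGQ = 1)
  expect_false(identical(b1$thresholds, b3$thresholds))
})

test_that("bootstrap spread shrinks with group size and with trial count", {
  trials <- sim_baseline(sigma_re = diag(c(0.02, 4)),
                         group_sizes = c(control = 8, migraine_aura = 8),
                         reps = 20, seed = 29)
  fit <- fit_probit_glmm(trials, nAGQ = 1)
  b_small <- bootstrap_threshold_sd(fit, baseline_only_design(20),
                                    n_samples = 50, seed = 3, nAGQ = 1)
  b_big <- bootstrap_threshold_sd(fit, baseline_only_design(20),
                                  n_samples = 50, seed = 3, nAGQ = 1,
                                  group_sizes = c(control = 32,
                                                  migraine_aura = 32))
  expect_true(all(b_big$sd < b_small$sd))

  # with no observer heterogeneity the spread comes from binomial sampling
  # alone and concentrates as repetitions grow
  zfit <- fit
  zfit$sigma_re_hat <- matrix(0, 2, 2)
  b_20 <- bootstrap_threshold_sd(zfit, baseline_only_design(20),
                                 n_samples = 15, seed = 5, nAGQ = 1)
  b_2k <- bootstrap_threshold_sd(zfit, baseline_only_design(2000),
                                 n_samples = 15, seed = 5, nAGQ = 1)
  expect_true(all(b_2k$sd < b_20$sd / 3))
})

test_that("the bootstrap group test is symmetric, bounded and sane", {
  mk_boot <- function(diffs) {
    B <- length(diffs)
    structure(list(
      thresholds = tibble::tibble(
        sample = rep(seq_len(B), each = 2),
        group = rep(c("control", "migraine_aura"), B),
        threshold = as.vector(rbind(0.04, 0.04 + diffs))
      ),
      observed = tibble::tibble(group = c("control", "migraine_aura"),
                                criterion = 0.75,
                                threshold = c(0.04, 0.04 + mean(diffs)))
    ), class = "threshold_bootstrap")
  }
  # every draw on one side: smallest attainable p
  b <- mk_boot(rep(-0.003, 40))
  expect_equal(compare_group_thresholds(b)$p.value, 2 / 41)
  # label swap leaves p unchanged
  swap <- mk_boot(rep(-0.003, 40))
  swap$thresholds$group <- rep(c("migraine_aura", "control"), 40)
  swap$observed$group <- rev(swap$observed$group)
  expect_equal(compare_group_thresholds(swap)$p.value,
               compare_group_thresholds(b)$p.value)
  # balanced draws: p capped at 1
  b0 <- mk_boot(c(rep(-0.001, 20), rep(0.001, 20)))
  expect_equal(compare_group_thresholds(b0)$p.value, 1)
  # single group errors
  solo <- mk_boot(rep(0.001, 10))
  solo$thresholds <- solo$thresholds[solo$thresholds$group == "control", ]
  expect_error(compare_group_thresholds(solo), "Both groups")
})

test_that("the full pipeline recovers generating thresholds", {
  beta <- c(-0.5, 29, -0.391, 12.313)
  th_true <- c(control = (qnorm(0.75) + 0.5) / 29,
               migraine_aura = (qnorm(0.75) + 0.5 + 0.391) / (29 + 12.313))
  trials <- sim_baseline(beta = beta, sigma_re = diag(c(0.04, 16)),
                         group_sizes = c(control = 31, migraine_aura = 24),
                         seed = 37)
  fit <- fit_probit_glmm(trials, nAGQ = 7)
  boot <- bootstrap_threshold_sd(fit, baseline_only_design(), n_samples = 40,
                                 seed = 11, nAGQ = 1)
  th_hat <- group_thresholds(fit)
  for (g in c("control", "migraine_aura")) {
    expect_lt(abs(th_hat$threshold[th_hat$group == g] - th_true[[g]]),
              3 * boot$sd[[g]])
  }
})

test_that("bootstrap guards its preconditions", {
  trials <- sim_baseline(group_sizes = c(control = 4, migraine_aura = 4),
                         seed = 43)
  fit <- fit_probit_glmm(trials, nAGQ = 1, compute_cov = FALSE)
  expect_error(bootstrap_threshold_sd(fit, covariance = "fixef",
                                      n_samples = 2),
               "cov_beta")
  nc <- fit
  nc$converged <- FALSE
  expect_error(bootstrap_threshold_sd(nc, n_samples = 2), "converged")
})
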