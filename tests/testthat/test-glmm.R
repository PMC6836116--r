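test_that("design matrices carry the specified terms", {
  trials <- sim_baseline(group_sizes = c(control = 4, migraine_aura = 3),
                         seed = 21)
  des <- build_design(trials, model_spec("baseline"))
  expect_equal(colnames(des$X),
               c("(Intercept)", "contrast", "group", "group:contrast"))
  expect_equal(nrow(des$X), 7 * 7)  # observers x levels, binomial coding
  expect_equal(sum(des$n), nrow(trials))

  pop <- population_params(group_sizes = c(control = 2, migraine_aura = 2))
  full <- simulate_dataset(pop, session_design(), seed = 22)
  fl <- build_design(dplyr::filter(full, condition != "baseline"),
                     model_spec("flanker"))
  expect_equal(ncol(fl$X), 8)
  expect_equal(colnames(fl$X),
               c("(Intercept)", "contrast", "group", "group:contrast",
                 "distance", "contrast:distance", "group:distance",
                 "group:distance:contrast"))
  expect_error(build_design(full, model_spec("flanker")),
               "baseline")

  bad <- trials
  bad$condition <- "nearby"
  expect_error(build_design(bad, model_spec("baseline")),
               "Unknown condition token")
  expect_error(
    build_design(dplyr::filter(trials, group == "control"),
                 model_spec("baseline")),
    "Single-group")
})

test_that("trial-level and aggregated codings give the same fit", {
  trials <- sim_baseline(sigma_re = diag(c(0.04, 4)),
                         group_sizes = c(control = 5, migraine_aura = 5),
                         seed = 31)
  f_bin <- fit_probit_glmm(trials, nAGQ = 5, coding = "binomial",
                           compute_cov = FALSE)
  f_ber <- fit_probit_glmm(trials, nAGQ = 5, coding = "bernoulli",
                           compute_cov = FALSE)
  expect_equal(f_ber$beta_hat, f_bin$beta_hat, tolerance = 1e-5)
  # the likelihood omits the data-only binomial coefficient, so the two
  # codings give the same value, not just the same maximizer
  expect_equal(f_bin$loglik, f_ber$loglik, tolerance = 1e-6)
})

test_that("the quadrature matches a brute-force integration oracle", {
  trials <- sim_baseline(sigma_re = diag(c(0.09, 9)),
                         group_sizes = c(control = 2, migraine_aura = 1),
                         reps = 10, seed = 41)
  des <- build_design(trials, model_spec("baseline"))
  beta <- c(-0.4, 25, -0.3, 10)
  sigma <- matrix(c(0.06, 0.3, 0.3, 9), 2, 2)
  ours <- probit_glmm_loglik(des, beta, sigma, nAGQ = 15)
  brute <- oracle_marginal_loglik(des, beta, sigma)
  expect_equal(ours, brute, tolerance = 1e-6)
})

test_that("with zero covariance the marginal likelihood is the GLM likelihood", {
  trials <- sim_baseline(group_sizes = c(control = 4, migraine_aura = 4),
                         seed = 51)
  des <- build_design(trials, model_spec("baseline"))
  beta <- c(-0.5, 29, -0.391, 12.313)
  for (nq in c(1, 7)) {
    expect_equal(probit_glmm_loglik(des, beta, matrix(0, 2, 2), nAGQ = nq),
                 oracle_probit_loglik(des$X, des$y, des$n, beta),
                 tolerance = 1e-10)
  }
})

test_that("quadrature order is converged at the default settings", {
  trials <- sim_baseline(sigma_re = diag(c(0.04, 16)),
                         group_sizes = c(control = 6, migraine_aura = 6),
                         seed = 61)
  fit <- fit_probit_glmm(trials, nAGQ = 7, compute_cov = FALSE)
  des <- fit$design
  ll5 <- probit_glmm_loglik(des, fit$beta_hat, fit$sigma_re_hat, nAGQ = 5)
  ll15 <- probit_glmm_loglik(des, fit$beta_hat, fit$sigma_re_hat, nAGQ = 15)
  expect_lt(abs(ll5 - ll15), 1e-4)
})

test_that("mixed-model fits agree with the direct-ML oracle when there is no heterogeneity", {
  trials <- sim_baseline(beta = c(-0.5, 29, 0, 0),
                         group_sizes = c(control = 6, migraine_aura = 6),
                         seed = 71)
  fit <- fit_probit_glmm(trials, nAGQ = 7)
  des <- fit$design
  orc <- oracle_probit_ml(des$X, des$y, des$n)
  se <- sqrt(diag(orc$cov))
  expect_true(all(abs(fit$beta_hat - orc$beta) < 2 * se))
  # optimizer contract: fitted deviance at least as good as the GLM start
  expect_gte(fit$loglik,
             probit_glmm_loglik(des, orc$beta, matrix(0, 2, 2), nAGQ = 7) - 1e-6)
  # estimated covariance is PSD by construction
  expect_true(min(eigen(fit$sigma_re_hat, symmetric = TRUE,
                        only.values = TRUE)$values) >= -1e-10)
})

test_that("random-effect variances are recovered on a larger simulation", {
  trials <- sim_baseline(beta = c(-0.5, 29, -0.4, 12),
                         sigma_re = diag(c(0.04, 16)),
                         group_sizes = c(control = 31, migraine_aura = 24),
                         seed = 81)
  fit <- fit_probit_glmm(trials, nAGQ = 7, compute_cov = FALSE)
  expect_true(fit$converged)
  expect_gt(fit$sigma_re_hat[2, 2], 1)   # slope heterogeneity detected
  expect_lt(fit$sigma_re_hat[2, 2], 80)
  expect_true(min(eigen(fit$sigma_re_hat, only.values = TRUE)$values) >= -1e-10)
})

test_that("Wald reports are internally consistent", {
  trials <- sim_baseline(group_sizes = c(control = 6, migraine_aura = 6),
                         sigma_re = diag(c(0.01, 4)), seed = 91)
  fit <- fit_probit_glmm(trials, nAGQ = 5)
  w <- wald_report(fit)
  expect_equal(w$statistic, w$estimate / w$std.error)
  expect_equal(w$df, rep(fit$n_obs - 4, 4))
  expect_equal(w$p.value, 2 * pt(-abs(w$statistic), w$df))
  expect_true(all(w$p.value >= 0 & w$p.value <= 1))
  expect_identical(tidy(fit), w)
  expect_equal(glance(fit)$logLik, fit$loglik)

  broken <- fit
  broken$cov_beta[1, 1] <- 0
  expect_error(wald_report(broken), "Zero or undefined")
  broken2 <- fit
  broken2$converged <- FALSE
  expect_error(wald_report(broken2), "converged")
})

test_that("the group-by-contrast Wald test holds its size under the null", {
  n_sim <- 120
  rej <- 0
  for (s in seq_len(n_sim)) {
    trials <- sim_baseline(beta = c(-0.5, 29, 0, 0),
                           sigma_re = diag(c(0.04, 9)),
                           group_sizes = c(control = 8, migraine_aura = 8),
                           seed = 1000 + s)
    fit <- fit_probit_glmm(trials, nAGQ = 1)
    if (!fit$converged || is.null(fit$cov_beta)) next
    w <- wald_report(fit)
    if (w$p.value[w$term == "group:contrast"] < 0.05) rej <- rej + 1
  }
  rate <- rej / n_sim
  # 0.05 plus/minus ~2 binomial SEs at 120 runs, and Laplace approximation slack
  expect_gt(rate, 0.0)
  expect_lt(rate, 0.12)
})

test_that("fitted psychometric predictions behave like a probit", {
  trials <- sim_baseline(group_sizes = c(control = 5, migraine_aura = 5),
                         seed = 101)
  fit <- fit_probit_glmm(trials, nAGQ = 3, compute_cov = FALSE)
  expect_equal(predict_p(fit, (qnorm(0.5) - fit$beta_hat[1]) / fit$beta_hat[2]),
               0.5, tolerance = 1e-12, ignore_attr = TRUE)
  cs <- seq(0, 0.2, length.out = 50)
  expect_true(all(diff(predict_p(fit, cs)) > 0))
  expect_equal(unname(predict_p(fit, 100)), 1, tolerance = 1e-8)
  # observer-level deviations shift the curve
  expect_gt(predict_p(fit, 0.02, observer_effects = c(1, 0)),
            predict_p(fit, 0.02))
})

test_that("separation and tiny samples are flagged", {
  trials <- sim_baseline(beta = c(8, 0, 0, 0),
                         group_sizes = c(control = 2, migraine_aura = 2),
                         reps = 5, seed = 111)
  expect_warning(fit_probit_glmm(trials, nAGQ = 1, compute_cov = FALSE),
                 "separation")
  one <- sim_baseline(group_sizes = c(control = 3, migraine_aura = 3),
                      seed = 112)
  one <- one[one$observer_id == one$observer_id[1], ]
  one$group <- rep(c("control", "migraine_aura"), length.out = nrow(one))
  # still a single observer: refuse
  expect_error(fit_probit_glmm(one, nAGQ = 1), "2 observers")
})
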