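# Independent oracles used to cross-check the package's estimators.
# These are deliberately simple, direct implementations that share no code
# with the package internals.

# Plain (no-random-effect) binomial probit regression by Newton-Raphson on
# the analytic score and observed information.
oracle_probit_ml <- function(X, y, n, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    P <- pnorm(eta)
    d <- dnorm(eta)
    r1 <- d / P
    r2 <- d / (1 - P)
    score <- as.numeric(t(X) %*% (y * r1 - (n - y) * r2))
    w <- -(y * (-eta * r1 - r1^2) + (n - y) * (eta * r2 - r2^2))
    H <- t(X) %*% (X * w)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(score)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  list(beta = beta,
       cov = solve(H),
       loglik = sum(y * pnorm(eta, log.p = TRUE) +
                      (n - y) * pnorm(-eta, log.p = TRUE)))
}

# Binomial probit log-likelihood at fixed beta (no random effects).
oracle_probit_loglik <- function(X, y, n, beta) {
  eta <- as.numeric(X %*% beta)
  sum(y * pnorm(eta, log.p = TRUE) + (n - y) * pnorm(-eta, log.p = TRUE))
}

# Brute-force marginal log-likelihood of the probit GLMM by 2-D trapezoid
# integration over the standardized random effect u ~ N(0, I), b = L u.
oracle_marginal_loglik <- function(des, beta, sigma_re,
                                   lim = 8, n_grid = 401) {
  L <- if (all(sigma_re == 0)) matrix(0, 2, 2) else t(chol(sigma_re))
  u <- seq(-lim, lim, length.out = n_grid)
  h <- u[2] - u[1]
  grid <- expand.grid(u1 = u, u2 = u)
  logphi <- dnorm(grid$u1, log = TRUE) + dnorm(grid$u2, log = TRUE)
  xb <- as.numeric(des$X %*% beta)
  total <- 0
  for (i in unique(des$obs_index)) {
    rows <- which(des$obs_index == i)
    b1 <- L[1, 1] * grid$u1
    b2 <- L[2, 1] * grid$u1 + L[2, 2] * grid$u2
    ll <- logphi
    for (j in rows) {
      eta <- xb[j] + b1 + des$Z[j, 2] * b2
      ll <- ll + des$y[j] * pnorm(eta, log.p = TRUE) +
        (des$n[j] - des$y[j]) * pnorm(-eta, log.p = TRUE)
    }
    m <- max(ll)
    total <- total + m + log(sum(exp(ll - m)) * h * h)
  }
  total
}

# Standard-normal quantile by bisection on pnorm.
oracle_qnorm_bisect <- function(p, tol = 1e-12) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Delta-method SE of the criterion threshold T = (qnorm(crit) - a) / b for a
# group, from the fixed-effect sampling covariance (term order: intercept,
# contrast, group, group:contrast).
oracle_threshold_se_delta <- function(beta, cov_beta, group,
                                      criterion = 0.75) {
  g <- as.numeric(group == "migraine_aura")
  a <- beta[1] + g * beta[3]
  b <- beta[2] + g * beta[4]
  T <- (qnorm(criterion) - a) / b
  grad <- c(-1 / b, -T / b, g * (-1 / b), g * (-T / b))
  sqrt(as.numeric(t(grad) %*% cov_beta %*% grad))
}

# A one-condition (baseline-only) session, for fitting studies that do not
# need the flanker blocks.
baseline_only_design <- function(reps = 20) {
  session_design(reps_per_level = reps, flanker_distances = numeric(0),
                 include_baseline = TRUE)
}

# Small simulated baseline dataset for two groups.
sim_baseline <- function(beta = c(-0.5, 29, 0, 0),
                         sigma_re = matrix(0, 2, 2),
                         group_sizes = c(control = 6, migraine_aura = 6),
                         reps = 20, seed = 1) {
  pop <- population_params(beta = beta, sigma_re = sigma_re,
                           group_sizes = group_sizes)
  simulate_dataset(pop, baseline_only_design(reps), seed = seed)
}
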