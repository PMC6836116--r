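#' Fit a binomial probit mixed-effects model by marginal maximum likelihood
#'
#' Maximizes the marginal likelihood of a probit-link binomial GLMM with a
#' bivariate per-observer random effect (intercept and contrast slope),
#' integrating the random effects out with adaptive Gauss-Hermite quadrature
#' (tensor-product nodes centred and scaled at each observer's conditional
#' mode). The random-effects covariance is parameterized by its Cholesky
#' factor, so the estimate is positive semi-definite by construction;
#' quadrature on the standardized scale remains exact when the covariance is
#' zero, where the marginal likelihood collapses to the plain probit GLM
#' likelihood.
#'
#' Start values are the plain probit GLM estimates for the fixed effects and
#' `0.1 * I` for the random-effects covariance. `nAGQ = 1` is the Laplace
#' approximation (fast mode, used for bootstrap refits).
#'
#' @param trials Trial tibble (see [simulate_dataset()]), or an `lm_design`
#'   bundle from [build_design()].
#' @param spec A [model_spec()]; ignored when `trials` is already a design
#'   bundle.
#' @param nAGQ Quadrature nodes per random-effect dimension (default 7;
#'   1 = Laplace).
#' @param coding Observation coding passed to [build_design()].
#' @param start Optional warm-start parameter vector
#'   `c(beta, l11, l21, l22)` (as stored in `$theta` of a previous fit).
#' @param compute_cov Compute the sampling covariance of the estimates from
#'   the inverse observed information (numerical Hessian)? Skipping it makes
#'   repeated refits (e.g. in the bootstrap) cheaper.
#' @param control Optimizer control overrides passed to [stats::nlminb()]
#'   (defaults: `rel.tol = 1e-10`, `iter.max = 500`, `eval.max = 2000`).
#'
#' @return An object of class `probit_glmm` with elements `beta_hat`,
#'   `cov_beta`, `sigma_re_hat`, `loglik`, `n_obs`, `n_observers`,
#'   `converged`, `n_iter`, `theta`, `spec`, and the design bundle.
#' @examples
#' pop <- population_params(group_sizes = c(control = 4, migraine_aura = 4))
#' trials <- simulate_dataset(pop, session_design(), seed = 1)
#' fit <- fit_probit_glmm(dplyr::filter(trials, condition == "baseline"),
#'                        nAGQ = 3, compute_cov = FALSE)
#' @export
fit_probit_glmm <- function(trials, spec = model_spec("baseline"),
                            nAGQ = 7, coding = c("binomial", "bernoulli"),
                            start = NULL, compute_cov = TRUE,
                            control = list()) {
  des <- if (inherits(trials, "lm_design")) trials else {
    build_design(trials, spec, coding = match.arg(coding))
  }
  if (length(des$observers) < 2) {
    abort("At least 2 observers are required to fit the mixed model.")
  }
  check_separation(des)
  p <- ncol(des$X)
  gh <- gauss_hermite(nAGQ)

  warm <- !is.null(start)
  if (is.null(start)) {
    g0 <- suppressWarnings(
      glm(cbind(des$y, des$n - des$y) ~ des$X - 1,
          family = binomial(link = "probit"))
    )
    start <- c(coef(g0), sqrt(0.1), 0, sqrt(0.1))
  }
  lower <- c(rep(-Inf, p), 0, -Inf, 0)
  upper <- rep(Inf, p + 3)
  # random-effect terms excluded from the spec are pinned at zero
  if (!"intercept" %in% des$spec$random_terms) {
    lower[p + 1] <- upper[p + 1] <- 0
    lower[p + 2] <- upper[p + 2] <- 0
    start[p + 1] <- start[p + 2] <- 0
  }
  if (!"contrast" %in% des$spec$random_terms) {
    lower[p + 2] <- upper[p + 2] <- 0
    lower[p + 3] <- upper[p + 3] <- 0
    start[p + 2] <- start[p + 3] <- 0
  }
  start <- pmin(pmax(start, lower), upper)

  negll <- function(theta) {
    agq_negloglik_cpp(theta, des$X, des$Z, des$obs_index, des$y, des$n,
                      gh$nodes, gh$weights)
  }
  ctrl <- utils::modifyList(
    list(rel.tol = 1e-10, iter.max = 500, eval.max = 2000), control)
  # PORT works much better when parameters are brought to a common scale
  # (contrast slopes are ~two orders larger than the covariance entries)
  port_scale <- function(at) 1 / pmax(abs(at), 0.1)
  if (nAGQ > 1 && !warm) {
    # pre-optimize under the cheap Laplace approximation, then refine with
    # the full quadrature from there
    gh1 <- gauss_hermite(1)
    opt0 <- nlminb(start,
                   function(theta) {
                     agq_negloglik_cpp(theta, des$X, des$Z, des$obs_index,
                                       des$y, des$n, gh1$nodes, gh1$weights)
                   },
                   scale = port_scale(start),
                   lower = lower, upper = upper, control = ctrl)
    if (all(is.finite(opt0$par))) start <- opt0$par
  }
  opt <- nlminb(start, negll, scale = port_scale(start),
                lower = lower, upper = upper, control = ctrl)
  # nlminb occasionally stops with "false convergence" on a flat stretch;
  # restarting from the current iterate usually clears it
  tries <- 0
  while (opt$convergence != 0 && tries < 2 && all(is.finite(opt$par))) {
    opt <- nlminb(opt$par, negll, scale = port_scale(opt$par),
                  lower = lower, upper = upper, control = ctrl)
    tries <- tries + 1
  }

  theta <- opt$par
  beta_hat <- setNames(theta[seq_len(p)], des$terms)
  L <- matrix(c(theta[p + 1], theta[p + 2], 0, theta[p + 3]), 2, 2)
  sigma_re_hat <- L %*% t(L)
  dimnames(sigma_re_hat) <- list(c("intercept", "contrast"),
                                 c("intercept", "contrast"))
  converged <- opt$convergence == 0 && all(is.finite(theta))

  cov_beta <- NULL
  if (compute_cov) {
    cov_beta <- observed_info_cov(negll, theta, p, lower, upper)
    dimnames(cov_beta) <- list(des$terms, des$terms)
  }

  structure(
    list(beta_hat = beta_hat, cov_beta = cov_beta,
         sigma_re_hat = sigma_re_hat, L = L, theta = theta,
         loglik = -opt$objective, n_obs = length(des$y),
         n_observers = length(des$observers),
         converged = converged, n_iter = opt$iterations,
         message = opt$message, spec = des$spec, design = des,
         nAGQ = nAGQ),
    class = "probit_glmm"
  )
}

# Warn about complete separation: an observer correct on every trial carries
# no information about its slope and can inflate random-effect estimates.
check_separation <- function(des) {
  tot <- tapply(des$y, des$obs_index, sum)
  n <- tapply(des$n, des$obs_index, sum)
  k <- sum(tot == n)
  if (k > 0) {
    warn(paste0(k, " observer(s) responded correctly on every trial ",
                "(complete separation); the fit proceeds but their random ",
                "effects are weakly identified."))
  }
  invisible(NULL)
}

# Sampling covariance of the fixed effects from the inverse observed
# information. Parameters sitting on the boundary of the Cholesky
# parameter space (pinned or estimated at zero variance) are profiled out of
# the Hessian rather than differenced across the boundary.
observed_info_cov <- function(negll, theta, p, lower, upper) {
  free <- which(upper > lower & !(seq_along(theta) > p &
                                    theta <= lower + 1e-6))
  f_free <- function(th_free) {
    th <- theta
    th[free] <- th_free
    negll(th)
  }
  H <- optimHess(theta[free], f_free)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V)[seq_len(p)] <= 0)) {
    # fall back to the beta block with the covariance parameters held fixed
    Hb <- optimHess(theta[seq_len(p)], function(b) negll(c(b, theta[-seq_len(p)])))
    Vb <- tryCatch(solve(Hb), error = function(e) {
      warn("Observed information is singular; covariance unavailable.")
      matrix(NA_real_, p, p)
    })
    return(Vb)
  }
  Vfull <- matrix(0, length(theta), length(theta))
  Vfull[free, free] <- V
  Vfull[seq_len(p), seq_len(p), drop = FALSE]
}

#' @export
print.probit_glmm <- function(x, ...) {
  cat("<probit_glmm> ", x$spec$model, " design, probit link, nAGQ = ",
      x$nAGQ, "\n", sep = "")
  cat("  observers:", x$n_observers, " rows:", x$n_obs,
      " logLik:", format(x$loglik, digits = 8),
      " converged:", x$converged, "\n")
  est <- data.frame(estimate = signif(x$beta_hat, 5))
  if (!is.null(x$cov_beta)) est$std.error <- signif(sqrt(diag(x$cov_beta)), 4)
  print(est)
  cat("  random-effects covariance (intercept, contrast slope):\n")
  print(signif(x$sigma_re_hat, 4))
  invisible(x)
}

#' @export
logLik.probit_glmm <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' Wald tests for the fixed effects
#'
#' Per-term estimates, standard errors (from the inverse observed
#' information), t statistics, residual degrees of freedom (rows of the model
#' frame minus the number of fixed-effect terms) and two-sided p values from
#' the t distribution.
#'
#' @param fit A converged [fit_probit_glmm()] result with `cov_beta`.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `df`, `p.value`.
#' @export
wald_report <- function(fit) {
  stopifnot(inherits(fit, "probit_glmm"))
  if (!isTRUE(fit$converged)) {
    abort("Wald tests require a converged fit.")
  }
  if (is.null(fit$cov_beta)) {
    abort("Fit was computed with `compute_cov = FALSE`; refit with covariance.")
  }
  se <- sqrt(diag(fit$cov_beta))
  if (any(!is.finite(se)) || any(se == 0)) {
    abort("Zero or undefined standard error; Wald statistics are not defined.")
  }
  df <- fit$n_obs - length(fit$beta_hat)
  stat <- unname(fit$beta_hat / se)
  tibble::tibble(
    term = names(fit$beta_hat),
    estimate = unname(fit$beta_hat),
    std.error = unname(se),
    statistic = stat,
    df = df,
    p.value = 2 * pt(-abs(stat), df)
  )
}

#' @export
tidy.probit_glmm <- function(x, ...) {
  wald_report(x)
}

#' @export
glance.probit_glmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    nobs = x$n_obs,
    n_observers = x$n_observers,
    sigma_intercept = sqrt(x$sigma_re_hat[1, 1]),
    sigma_contrast = sqrt(x$sigma_re_hat[2, 2]),
    re_correlation = {
      s <- sqrt(diag(x$sigma_re_hat))
      if (all(s > 0)) x$sigma_re_hat[1, 2] / prod(s) else NA_real_
    },
    converged = x$converged,
    n_iter = x$n_iter
  )
}

# (intercept, slope) of the population-average psychometric function for a
# group, optionally at a flanker distance (flanker model only).
group_int_slope <- function(fit, group, distance = NULL) {
  b <- fit$beta_hat
  g <- as.numeric(group == "migraine_aura")
  if (fit$spec$model == "baseline") {
    if (!is.null(distance)) {
      abort("The baseline model has no distance term.")
    }
    c(intercept = unname(b["(Intercept)"] + g * b["group"]),
      slope = unname(b["contrast"] + g * b["group:contrast"]))
  } else {
    if (is.null(distance)) {
      abort("The flanker model needs a `distance` (in wavelengths).")
    }
    d <- as.numeric(distance)
    c(intercept = unname(b["(Intercept)"] + g * b["group"] +
                           d * b["distance"] + g * d * b["group:distance"]),
      slope = unname(b["contrast"] + g * b["group:contrast"] +
                       d * b["contrast:distance"] +
                       g * d * b["group:distance:contrast"]))
  }
}

#' Predicted probability of a correct response
#'
#' Evaluates the fitted psychometric function `pnorm(eta)` at given
#' covariates, for the population-average curve or, if `observer_effects`
#' is supplied, for an individual observer.
#'
#' @param fit A [fit_probit_glmm()] result.
#' @param contrast Michelson contrast value(s).
#' @param group `"control"` or `"migraine_aura"`.
#' @param distance Flanker distance in wavelengths (flanker model only).
#' @param observer_effects Optional length-2 numeric `(intercept, slope)`
#'   deviation added to the group-level curve.
#' @return Probabilities in `[0, 1]`, monotone in contrast when the total
#'   contrast coefficient is positive.
#' @export
predict_p <- function(fit, contrast, group = "control", distance = NULL,
                      observer_effects = NULL) {
  stopifnot(inherits(fit, "probit_glmm"))
  group <- match.arg(group, group_levels)
  ab <- group_int_slope(fit, group, distance)
  if (!is.null(observer_effects)) {
    stopifnot(length(observer_effects) == 2, all(is.finite(observer_effects)))
    ab <- ab + as.numeric(observer_effects)
  }
  pnorm(ab[["intercept"]] + ab[["slope"]] * contrast)
}

#' Marginal log-likelihood at given parameters
#'
#' Evaluates the quadrature-based marginal log-likelihood of the probit GLMM
#' at user-supplied fixed effects and random-effects covariance, without
#' optimizing. With `sigma_re = 0` this equals the plain probit GLM
#' log-likelihood exactly.
#'
#' @inheritParams fit_probit_glmm
#' @param beta Fixed-effect vector in the order of `spec$fixed_terms`.
#' @param sigma_re 2x2 PSD random-effects covariance.
#' @return The marginal log-likelihood (a scalar).
#' @export
probit_glmm_loglik <- function(trials, beta, sigma_re,
                               spec = model_spec("baseline"), nAGQ = 7,
                               coding = c("binomial", "bernoulli")) {
  des <- if (inherits(trials, "lm_design")) trials else {
    build_design(trials, spec, coding = match.arg(coding))
  }
  check_psd(as.matrix(sigma_re), "sigma_re")
  stopifnot(length(beta) == ncol(des$X))
  L <- if (all(sigma_re == 0)) matrix(0, 2, 2) else t(chol(sigma_re))
  gh <- gauss_hermite(nAGQ)
  agq_loglik_cpp(as.numeric(beta), c(L[1, 1], L[2, 1], L[2, 2]),
                 des$X, des$Z, des$obs_index, des$y, des$n,
                 gh$nodes, gh$weights)
}
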