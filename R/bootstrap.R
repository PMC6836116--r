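#' Parametric bootstrap of group threshold uncertainty
#'
#' Implements the simulated-observer bootstrap for the standard deviation of
#' the group 75% thresholds. Each bootstrap sample (1) draws per-observer
#' probit intercepts and contrast slopes from the fitted group-level
#' estimates and a covariance, (2) simulates binomial responses at every
#' contrast level of the design through the probit function, (3) refits the
#' same mixed model to the simulated data, and (4) records each group's
#' criterion threshold from the refitted fixed effects. The spread of the
#' recorded thresholds estimates the sampling uncertainty of the group
#' thresholds.
#'
#' Two interpretations of "the covariance" used in step (1) are supported:
#'
#' * `"ranef"` (default): per-observer draws around the group means with the
#'   fitted random-effects covariance — a population of heterogeneous
#'   simulated observers, re-enacting the whole experiment.
#' * `"fixef"`: one (intercept, slope) pair per group per bootstrap sample,
#'   drawn from the fixed-effect sampling covariance and shared by all of
#'   the group's observers — propagating estimation uncertainty only. In the
#'   zero-heterogeneity regime with many trials this reproduces the
#'   delta-method standard error of the threshold.
#'
#' Non-convergent refits are dropped and counted, never imputed; more than
#' 20% dropped aborts with advice.
#'
#' @param fit A converged baseline-model [fit_probit_glmm()] (with
#'   `cov_beta` when `covariance = "fixef"`).
#' @param design A [session_design()] giving the contrast levels and
#'   repetitions simulated in step (2).
#' @param n_samples Number of bootstrap samples (default 1000).
#' @param seed Integer seed; the summary is reproducible given the seed.
#' @param covariance `"ranef"` or `"fixef"` (see Details).
#' @param group_sizes Optional named sizes of the simulated groups; defaults
#'   to the observer counts of the original fit.
#' @param nAGQ Quadrature order for the refits; defaults to the original
#'   fit's order. `nAGQ = 1` (Laplace) is the fast mode.
#' @param criterion Criterion probability (default 0.75).
#'
#' @return An object of class `threshold_bootstrap`: the per-sample group
#'   thresholds, per-group SDs, dropped-refit count, seed and settings.
#' @seealso [compare_group_thresholds()] for the bootstrap group test.
#' @export
bootstrap_threshold_sd <- function(fit, design = session_design(),
                                   n_samples = 1000, seed = 1L,
                                   covariance = c("ranef", "fixef"),
                                   group_sizes = NULL, nAGQ = NULL,
                                   criterion = 0.75) {
  stopifnot(inherits(fit, "probit_glmm"), inherits(design, "session_design"))
  covariance <- match.arg(covariance)
  if (fit$spec$model != "baseline") {
    abort("The threshold bootstrap is defined for the baseline model.")
  }
  if (!isTRUE(fit$converged)) {
    abort("The bootstrap requires a converged fit.")
  }
  if (covariance == "fixef" && is.null(fit$cov_beta)) {
    abort("`covariance = \"fixef\"` needs the fit's `cov_beta`; refit with `compute_cov = TRUE`.")
  }
  if (is.null(group_sizes)) {
    group_sizes <- table(fit$design$groups)[group_levels]
    group_sizes <- setNames(as.integer(group_sizes), group_levels)
  }
  if (any(is.na(group_sizes)) || any(group_sizes < 1)) {
    abort("Both groups need a positive simulated size.")
  }
  nAGQ <- nAGQ %||% fit$nAGQ
  mu <- rbind(control = group_int_slope(fit, "control"),
              migraine_aura = group_int_slope(fit, "migraine_aura"))
  re_root <- psd_sqrt(fit$sigma_re_hat)
  fix_root <- if (covariance == "fixef") {
    A <- list(control = rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
              migraine_aura = rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
    lapply(A, function(a) psd_sqrt(a %*% fit$cov_beta %*% t(a)))
  }

  groups <- rep(group_levels, group_sizes)
  n_obs <- length(groups)
  lv <- design$contrast_levels
  reps <- design$reps_per_level

  one_sample <- function(s) {
    withr_seed(derive_seed(seed, s), {
      if (covariance == "ranef") {
        dev <- matrix(rnorm(2L * n_obs), ncol = 2) %*% t(re_root)
        ab <- mu[groups, , drop = FALSE] + dev
      } else {
        gdev <- lapply(group_levels, function(g) {
          mu[g, ] + as.numeric(fix_root[[g]] %*% rnorm(2))
        })
        names(gdev) <- group_levels
        ab <- do.call(rbind, gdev[groups])
      }
      eta <- ab[, 1] + outer(ab[, 2], lv)       # observers x levels
      y <- rbinom(length(eta), reps, pnorm(as.numeric(eta)))
      cells_g <- rep(groups, times = length(lv))
      des <- cell_design(
        observer_id = rep(sprintf("B%04d", seq_len(n_obs)), times = length(lv)),
        group = cells_g,
        contrast = rep(lv, each = n_obs),
        y = y, n = reps, spec = fit$spec
      )
      refit <- fit_probit_glmm(des, nAGQ = nAGQ, start = fit$theta,
                               compute_cov = FALSE)
      if (!refit$converged) {
        # retry once from cold start before declaring the refit lost
        refit <- fit_probit_glmm(des, nAGQ = nAGQ, compute_cov = FALSE)
      }
      if (!refit$converged) return(NULL)
      th <- group_thresholds(refit, criterion = criterion)
      setNames(th$threshold, th$group)
    })
  }
  draws <- suppressWarnings(purrr::map(seq_len(n_samples), one_sample))
  dropped <- sum(purrr::map_lgl(draws, is.null))
  if (dropped > 0.2 * n_samples) {
    abort(paste0(dropped, "/", n_samples, " bootstrap refits failed to ",
                 "converge; use more data per observer or the Laplace fast ",
                 "mode (nAGQ = 1)."))
  }
  kept <- which(!purrr::map_lgl(draws, is.null))
  thresholds <- tibble::tibble(
    sample = rep(kept, each = 2),
    group = rep(group_levels, times = length(kept)),
    threshold = unlist(lapply(draws[kept], function(d) d[group_levels]),
                       use.names = FALSE)
  )
  sds <- thresholds |>
    dplyr::summarise(sd = sd(.data$threshold), .by = "group")
  structure(
    list(thresholds = thresholds,
         sd = setNames(sds$sd, sds$group),
         n_samples = length(kept), n_requested = n_samples,
         n_dropped = dropped, seed = seed, covariance = covariance,
         criterion = criterion, nAGQ = nAGQ,
         group_sizes = group_sizes,
         observed = group_thresholds(fit, criterion = criterion)),
    class = "threshold_bootstrap"
  )
}

# Assemble an lm_design bundle directly from binomial cells (internal fast
# path used by the bootstrap; bypasses trial-level expansion).
cell_design <- function(observer_id, group, contrast, y, n, spec) {
  ord <- order(observer_id, contrast)
  observer_id <- observer_id[ord]
  group <- group[ord]
  contrast <- contrast[ord]
  g <- as.numeric(group == "migraine_aura")
  X <- cbind("(Intercept)" = 1, contrast = contrast, group = g,
             "group:contrast" = g * contrast)
  observers <- unique(observer_id)
  structure(
    list(X = X,
         Z = cbind(intercept = rep(1, length(contrast)), contrast = contrast),
         obs_index = match(observer_id, observers) - 1L,
         y = as.numeric(y[ord]), n = rep(as.numeric(n), length.out = length(y)),
         terms = colnames(X), observers = observers,
         groups = group[match(observers, observer_id)],
         coding = "binomial", spec = spec),
    class = "lm_design"
  )
}

#' @export
print.threshold_bootstrap <- function(x, ...) {
  cat("<threshold_bootstrap> B =", x$n_samples, "kept /", x$n_requested,
      "requested (", x$n_dropped, "non-convergent dropped ),",
      "covariance mode:", x$covariance, "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.threshold_bootstrap <- function(x, ...) {
  x$thresholds |>
    dplyr::summarise(mean = mean(.data$threshold),
                     sd = sd(.data$threshold),
                     n = dplyr::n(), .by = "group") |>
    dplyr::left_join(
      dplyr::select(x$observed, "group", observed = "threshold"),
      by = "group"
    ) |>
    dplyr::relocate("group", "observed")
}

#' @export
glance.threshold_bootstrap <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_requested = x$n_requested,
                 n_dropped = x$n_dropped, covariance = x$covariance,
                 criterion = x$criterion, seed = x$seed)
}

#' Bootstrap test for a group difference in thresholds
#'
#' Two-sided bootstrap p value for the difference in group thresholds
#' (migraine-with-aura minus control), computed from the per-sample
#' difference distribution as `2 * min(Pr(diff <= 0), Pr(diff >= 0))` with
#' the `(k + 1) / (B + 1)` continuity correction, so the p value is never
#' exactly zero and is invariant to swapping the group labels.
#'
#' @param boot A [bootstrap_threshold_sd()] summary containing both groups.
#' @return A tibble with `estimate` (observed threshold difference), the
#'   bootstrap mean difference, `p.value` and the number of samples.
#' @export
compare_group_thresholds <- function(boot) {
  stopifnot(inherits(boot, "threshold_bootstrap"))
  wide <- tidyr::pivot_wider(boot$thresholds, names_from = "group",
                             values_from = "threshold")
  if (!all(group_levels %in% names(wide))) {
    abort("Both groups must be present in the bootstrap summary.")
  }
  d <- wide$migraine_aura - wide$control
  B <- length(d)
  p <- 2 * min(sum(d <= 0) + 1, sum(d >= 0) + 1) / (B + 1)
  obs <- tidyr::pivot_wider(boot$observed, names_from = "group",
                            values_from = "threshold",
                            id_cols = "criterion")
  tibble::tibble(
    estimate = obs$migraine_aura - obs$control,
    boot_mean = mean(d),
    boot_sd = sd(d),
    p.value = min(p, 1),
    n_samples = B
  )
}
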