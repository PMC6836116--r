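#' Generative observer population
#'
#' Defines the population that synthetic observers are drawn from: group-level
#' fixed effects on the probit scale plus a 2x2 covariance of per-observer
#' (intercept, contrast-slope) deviations. An observer's psychometric function
#' is `P(correct) = pnorm(intercept + slope * contrast)`.
#'
#' The fixed-effect vector is ordered `(intercept, contrast_slope,
#' group_intercept_offset, group_slope_offset)`: control observers are centred
#' on `(beta[1], beta[2])` and migraine-with-aura observers on
#' `(beta[1] + beta[3], beta[2] + beta[4])`. The defaults follow the fitted
#' baseline coefficients of the study this package models (contrast slope
#' 29.141, group offset -0.391, group-by-contrast offset 12.313; the intercept,
#' which the source analysis does not print, defaults to -0.5, placing the
#' control 75% threshold near 0.04 Michelson contrast), with group sizes 31
#' controls and 24 migraine-with-aura.
#'
#' `condition_effects` is an optional named vector of per-condition probit
#' intercept offsets (names are condition tokens, e.g. `"1"`, `"12"`,
#' `"baseline"`). It exists so flanker facilitation/inhibition scenarios can be
#' simulated: a positive offset raises performance in that block and so lowers
#' its threshold (facilitation).
#'
#' @param beta Numeric length-4 fixed-effect vector (see Details).
#' @param sigma_re Symmetric positive semi-definite 2x2 covariance of
#'   per-observer (intercept, slope) deviations.
#' @param group_sizes Named or unnamed length-2 integer vector: number of
#'   control and migraine-with-aura observers.
#' @param condition_effects Optional named numeric vector of per-condition
#'   intercept offsets; conditions not named get offset 0.
#'
#' @return An object of class `population_params`.
#' @examples
#' pop <- population_params()
#' obs <- draw_observers(pop, seed = 1)
#' @export
population_params <- function(beta = c(-0.5, 29.141, -0.391, 12.313),
                              sigma_re = diag(c(0.04, 16)),
                              group_sizes = c(control = 31, migraine_aura = 24),
                              condition_effects = NULL) {
  if (!is.numeric(beta) || length(beta) != 4 || any(!is.finite(beta))) {
    abort("`beta` must be a finite numeric vector of length 4.")
  }
  sigma_re <- as.matrix(sigma_re)
  check_psd(sigma_re, "sigma_re")
  if (length(group_sizes) != 2 || any(group_sizes < 1) ||
      any(group_sizes != round(group_sizes))) {
    abort("`group_sizes` must be two integers >= 1 (control, migraine_aura).")
  }
  group_sizes <- as.integer(group_sizes)
  names(group_sizes) <- c("control", "migraine_aura")
  if (!is.null(condition_effects)) {
    if (is.null(names(condition_effects)) || any(names(condition_effects) == "")) {
      abort("`condition_effects` must be a fully named numeric vector.")
    }
    condition_effects <- setNames(as.numeric(condition_effects),
                                  names(condition_effects))
  }
  structure(
    list(beta = as.numeric(beta), sigma_re = sigma_re,
         group_sizes = group_sizes, condition_effects = condition_effects),
    class = "population_params"
  )
}

# Validates symmetry/PSD; error message names the offending matrix.
check_psd <- function(m, label, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != 2 || ncol(m) != 2 || any(!is.finite(m))) {
    abort(paste0("`", label, "` must be a finite 2x2 matrix."))
  }
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    abort(paste0("`", label, "` is not symmetric."))
  }
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    abort(paste0("`", label, "` is not positive semi-definite (eigenvalues ",
                 paste(signif(ev, 4), collapse = ", "), ")."))
  }
  invisible(m)
}

# Symmetric PSD square root; works for singular (incl. zero) matrices,
# where chol() would fail.
psd_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m)) %*% t(e$vectors)
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params>\n")
  cat("  beta (int, slope, grp, grp:slope):",
      paste(signif(x$beta, 5), collapse = ", "), "\n")
  cat("  sigma_re: [", x$sigma_re[1, 1], x$sigma_re[1, 2], ";",
      x$sigma_re[2, 1], x$sigma_re[2, 2], "]\n")
  cat("  group sizes:", paste(names(x$group_sizes), x$group_sizes,
                              collapse = ", "), "\n")
  if (!is.null(x$condition_effects)) {
    cat("  condition effects:",
        paste(names(x$condition_effects), signif(x$condition_effects, 3),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Draw a population of simulated observers
#'
#' Draws per-observer probit intercepts and contrast slopes: each observer's
#' `(intercept, slope)` is the group-specific fixed effect plus a zero-mean
#' bivariate-normal deviation with covariance `pop$sigma_re`. With a zero
#' covariance every observer in a group is identical to the group mean.
#'
#' @param pop A [population_params()].
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return A tibble with one row per observer: `observer_id`, `group`,
#'   `intercept`, `contrast_slope`.
#' @export
draw_observers <- function(pop, seed = 1L) {
  stopifnot(inherits(pop, "population_params"))
  n <- sum(pop$group_sizes)
  groups <- rep(names(pop$group_sizes), pop$group_sizes)
  mu <- cbind(
    ifelse(groups == "control", pop$beta[1], pop$beta[1] + pop$beta[3]),
    ifelse(groups == "control", pop$beta[2], pop$beta[2] + pop$beta[4])
  )
  root <- psd_sqrt(pop$sigma_re)
  dev <- withr_seed(seed, matrix(rnorm(2L * n), nrow = n) %*% t(root))
  tibble::tibble(
    observer_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    intercept = mu[, 1] + dev[, 1],
    contrast_slope = mu[, 2] + dev[, 2]
  )
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

# Splittable counter scheme: one master seed expands to per-(observer, block)
# streams so any subset of the simulation is reproducible in isolation.
# A 31-bit multiplicative mix of the master seed and the integer keys.
derive_seed <- function(master, ...) {
  keys <- c(...)
  s <- as.double(master %% 2147483647)
  for (k in keys) {
    s <- (s * 48271 + (as.double(k) + 1) * 16807) %% 2147483647
  }
  as.integer(s)
}
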