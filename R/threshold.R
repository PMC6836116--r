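#' Contrast threshold at a criterion performance level
#'
#' Inverts the probit psychometric function `P(correct) = pnorm(intercept +
#' slope * contrast)` at a criterion probability (default 0.75, the
#' conventional 2AFC threshold): `threshold = (qnorm(criterion) - intercept)
#' / slope`.
#'
#' @param intercept Probit-scale intercept.
#' @param slope Probit units per unit Michelson contrast; must be non-zero.
#' @param criterion Criterion probability in (0, 1); default 0.75.
#' @return The contrast at criterion (same length as the inputs, recycled).
#' @examples
#' threshold_75(-0.5, 29)         # ~0.0405
#' threshold_75(0, 1, criterion = 0.5)  # 0
#' @export
threshold_75 <- function(intercept, slope, criterion = 0.75) {
  if (any(!is.finite(intercept)) || any(!is.finite(slope))) {
    abort("`intercept` and `slope` must be finite.")
  }
  if (any(criterion <= 0 | criterion >= 1)) {
    abort("`criterion` must lie strictly in (0, 1).")
  }
  if (any(slope == 0)) {
    abort("threshold undefined: psychometric slope is zero.")
  }
  if (any(slope < 0)) {
    warn(paste0("Negative psychometric slope: performance decreases with ",
                "contrast; the returned threshold is degenerate."))
  }
  (qnorm(criterion) - intercept) / slope
}

#' Group-level thresholds from a fitted model
#'
#' Computes each group's criterion-contrast threshold from the
#' population-average fixed effects of a fitted probit mixed model (the
#' group-level intercept and slope; random effects enter the threshold only
#' through their effect on the fixed-effect estimates).
#'
#' @param fit A [fit_probit_glmm()] result.
#' @param criterion Criterion probability (default 0.75).
#' @param distance Flanker distance(s) at which to evaluate a flanker-model
#'   fit; must be `NULL` for a baseline-model fit.
#' @return A tibble with columns `group`, (`distance`,) `criterion`,
#'   `threshold`.
#' @export
group_thresholds <- function(fit, criterion = 0.75, distance = NULL) {
  stopifnot(inherits(fit, "probit_glmm"))
  if (fit$spec$model == "baseline") {
    if (!is.null(distance)) abort("The baseline model has no distance term.")
    grid <- tidyr::expand_grid(group = group_levels)
  } else {
    if (is.null(distance)) {
      abort("Supply `distance` (wavelengths) to evaluate a flanker-model fit.")
    }
    grid <- tidyr::expand_grid(group = group_levels, distance = as.numeric(distance))
  }
  th <- purrr::pmap_dbl(grid, function(group, distance = NULL) {
    ab <- group_int_slope(fit, group, distance)
    threshold_75(ab[["intercept"]], ab[["slope"]], criterion)
  })
  dplyr::mutate(grid, criterion = criterion, threshold = th)
}
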