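#' Classify a relative threshold as facilitation or inhibition
#'
#' A flanker-condition threshold divided by the no-flanker baseline threshold
#' is below 1 when the flankers helped detection (facilitation) and above 1
#' when they hindered it (inhibition). An optional tolerance half-width
#' around 1 maps near-unity ratios to `"none"`.
#'
#' @param relative_value Positive threshold ratio(s).
#' @param tolerance Half-width of the `"none"` band around 1 (default 0,
#'   strict classification).
#' @return Character vector: `"facilitation"`, `"inhibition"` or `"none"`.
#' @examples
#' classify_interaction(c(0.7, 1, 1.5))
#' @export
classify_interaction <- function(relative_value, tolerance = 0) {
  if (any(!is.finite(relative_value)) || any(relative_value <= 0)) {
    abort("`relative_value` must be positive and finite.")
  }
  stopifnot(tolerance >= 0)
  dplyr::case_when(
    relative_value > 1 + tolerance ~ "inhibition",
    relative_value < 1 - tolerance ~ "facilitation",
    .default = "none"
  )
}

#' Normalize condition thresholds by a group's baseline threshold
#'
#' Divides each flanker-condition threshold by the same group's no-flanker
#' baseline threshold. Normalization is strictly within group: the baseline
#' row must carry the same group label as every condition row.
#'
#' @param condition_thresholds Tibble of per-condition estimates with columns
#'   `group`, `distance` and `threshold` (and optionally `sd`).
#' @param baseline A one-row tibble (or list) with the same group's `group`
#'   and baseline `threshold` (optionally `sd`).
#' @param tolerance Classification tolerance passed to
#'   [classify_interaction()].
#' @return A tibble with `group`, `distance`, `threshold`,
#'   `baseline_threshold`, `relative_threshold` and `classification`.
#' @export
normalize_thresholds <- function(condition_thresholds, baseline,
                                 tolerance = 0) {
  baseline <- as.list(baseline)
  if (!is.finite(baseline$threshold) || baseline$threshold <= 0) {
    abort("Baseline threshold must be strictly positive.")
  }
  if (!all(condition_thresholds$group == baseline$group)) {
    abort(paste0("Normalization is within-group: condition thresholds and ",
                 "baseline must come from the same group."))
  }
  condition_thresholds |>
    dplyr::mutate(
      baseline_threshold = baseline$threshold,
      relative_threshold = .data$threshold / baseline$threshold,
      classification = classify_interaction(.data$relative_threshold,
                                            tolerance)
    )
}

#' Facilitation/inhibition profile across flanker distances
#'
#' End-to-end lateral-interaction analysis of a trial table: fits the probit
#' mixed model, extracts each group's criterion threshold per flanker
#' distance, and normalizes by the group's own no-flanker baseline
#' threshold. Two fitting modes are available:
#'
#' * `"per_condition"` (default): one baseline-structure fit per condition
#'   block (including the baseline block), each yielding group thresholds.
#' * `"joint"`: a single flanker-model fit (distance and its interactions as
#'   fixed effects) over all flanker blocks, evaluated at each distance;
#'   the baseline block is still fit separately for the normalizer.
#'
#' With `n_boot > 0` each per-condition fit is bootstrapped
#' ([bootstrap_threshold_sd()]) and the relative-threshold SD is computed
#' from samplewise ratios of condition to baseline bootstrap draws.
#'
#' @param trials Trial tibble containing a `"baseline"` block and at least
#'   one flanker block for both groups.
#' @param mode `"per_condition"` or `"joint"`.
#' @param criterion Criterion probability (default 0.75).
#' @param nAGQ Quadrature order for the fits.
#' @param n_boot Bootstrap samples per condition for threshold SDs
#'   (0 = no bootstrap, `sd` is `NA`).
#' @param boot_nAGQ Quadrature order for bootstrap refits (default 1,
#'   Laplace fast mode).
#' @param design Session design used by the bootstrap simulation step;
#'   defaults to the levels/repetitions of the default session.
#' @param seed Integer seed for the bootstrap streams.
#' @param tolerance Classification tolerance around 1.
#' @return A tibble of class `facilitation_profile`: `group`, `distance`,
#'   `threshold`, `baseline_threshold`, `relative_threshold`, `sd`,
#'   `classification`; fit diagnostics in `attr(, "fits")`.
#' @export
facilitation_profile <- function(trials, mode = c("per_condition", "joint"),
                                 criterion = 0.75, nAGQ = 7, n_boot = 0,
                                 boot_nAGQ = 1, design = session_design(),
                                 seed = 1L, tolerance = 0) {
  mode <- match.arg(mode)
  validate_trials(trials)
  conds <- unique(as.character(trials$condition))
  if (!"baseline" %in% conds) {
    abort("Trial table has no 'baseline' block; the profile is undefined.")
  }
  dists <- sort(as.numeric(setdiff(conds, "baseline")))
  if (length(dists) == 0) {
    abort("Trial table has no flanker block; nothing to normalize.")
  }

  fit_block <- function(cond) {
    fit_probit_glmm(dplyr::filter(trials, as.character(.data$condition) == cond),
                    model_spec("baseline"), nAGQ = nAGQ, compute_cov = FALSE)
  }

  boot_block <- function(fit, cond_key) {
    if (n_boot <= 0) return(NULL)
    bootstrap_threshold_sd(fit, design = design, n_samples = n_boot,
                           seed = derive_seed(seed, match(cond_key, conds)),
                           nAGQ = boot_nAGQ, criterion = criterion)
  }

  base_fit <- fit_block("baseline")
  base_boot <- boot_block(base_fit, "baseline")
  base_th <- group_thresholds(base_fit, criterion = criterion)

  if (mode == "per_condition") {
    cond_fits <- lapply(as.character(dists), fit_block)
    names(cond_fits) <- as.character(dists)
    cond_th <- purrr::imap(cond_fits, function(f, d) {
      dplyr::mutate(group_thresholds(f, criterion = criterion),
                    distance = as.numeric(d))
    }) |> purrr::list_rbind()
    cond_boot <- purrr::imap(cond_fits, boot_block)
  } else {
    joint_fit <- fit_probit_glmm(
      dplyr::filter(trials, .data$condition != "baseline"),
      model_spec("flanker"), nAGQ = nAGQ, compute_cov = FALSE)
    cond_fits <- list(joint = joint_fit)
    cond_th <- group_thresholds(joint_fit, criterion = criterion,
                                distance = dists)
    cond_boot <- NULL
  }

  profile <- purrr::map(group_levels, function(g) {
    normalize_thresholds(
      dplyr::filter(cond_th, .data$group == g) |>
        dplyr::select("group", "distance", "threshold"),
      dplyr::filter(base_th, .data$group == g),
      tolerance = tolerance
    )
  }) |> purrr::list_rbind()

  profile$sd <- NA_real_
  if (n_boot > 0 && mode == "per_condition") {
    for (i in seq_len(nrow(profile))) {
      g <- profile$group[i]
      bb <- cond_boot[[as.character(profile$distance[i])]]
      num <- dplyr::filter(bb$thresholds, .data$group == g)$threshold
      den <- dplyr::filter(base_boot$thresholds, .data$group == g)$threshold
      m <- min(length(num), length(den))
      profile$sd[i] <- sd(num[seq_len(m)] / den[seq_len(m)])
    }
  }
  profile <- dplyr::relocate(profile, "group", "distance", "threshold",
                             "baseline_threshold", "relative_threshold",
                             "sd", "classification")
  structure(
    profile,
    fits = c(list(baseline = base_fit), cond_fits),
    mode = mode, criterion = criterion, seed = seed,
    class = c("facilitation_profile", class(profile))
  )
}

#' @rdname facilitation_profile
#' @param object,x A `facilitation_profile`.
#' @param ... Unused.
#' @export
autoplot.facilitation_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$distance,
                               y = .data$relative_threshold,
                               colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 1, colour = "black") +
    {
      if (any(is.finite(object$sd)))
        ggplot2::geom_errorbar(
          ggplot2::aes(ymin = .data$relative_threshold - .data$sd,
                       ymax = .data$relative_threshold + .data$sd),
          width = 0.2)
    } +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Flanker distance (wavelengths)",
                  y = "Relative 75% threshold",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' @rdname facilitation_profile
#' @export
plot.facilitation_profile <- function(x, ...) print(autoplot(x, ...))
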