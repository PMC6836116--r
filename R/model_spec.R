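#' Model specification for the probit mixed-effects analyses
#'
#' Two canonical fixed-effect structures are supported, mirroring the two
#' analyses of the lateral-masking design:
#'
#' * `"baseline"` — contrast as a fixed covariate, group as a categorical
#'   factor (control = reference) and their interaction:
#'   `(Intercept) + contrast + group + group:contrast` (4 columns).
#' * `"flanker"` — adds flanker distance (in wavelength units) and its
#'   interactions: `distance`, `contrast:distance`, `group:distance` and
#'   `group:distance:contrast` (8 columns). Fit to flanker blocks only; the
#'   no-flanker baseline block has no distance coordinate.
#'
#' Both use a probit link and per-observer random effects on the intercept
#' and/or the contrast slope.
#'
#' @param model `"baseline"` or `"flanker"`.
#' @param random_terms Random-effect structure per observer: subset of
#'   `c("intercept", "contrast")`; default both (random intercepts and
#'   contrast slopes).
#' @return An object of class `lm_model_spec`.
#' @examples
#' model_spec("baseline")
#' @export
model_spec <- function(model = c("baseline", "flanker"),
                       random_terms = c("intercept", "contrast")) {
  model <- match.arg(model)
  random_terms <- match.arg(random_terms, several.ok = TRUE)
  fixed_terms <- switch(model,
    baseline = c("(Intercept)", "contrast", "group", "group:contrast"),
    flanker = c("(Intercept)", "contrast", "group", "group:contrast",
                "distance", "contrast:distance", "group:distance",
                "group:distance:contrast")
  )
  structure(
    list(model = model, fixed_terms = fixed_terms,
         random_terms = random_terms, link = "probit"),
    class = "lm_model_spec"
  )
}

#' @export
print.lm_model_spec <- function(x, ...) {
  cat("<lm_model_spec> probit,", x$model, "design\n")
  cat("  fixed :", paste(x$fixed_terms, collapse = " + "), "\n")
  cat("  random:", paste(x$random_terms, collapse = " + "),
      "(per observer)\n")
  invisible(x)
}

group_levels <- c("control", "migraine_aura")

validate_trials <- function(trials, require_correct = TRUE) {
  needed <- c("observer_id", "group", "condition", "contrast",
              if (require_correct) "correct")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    abort(paste0("Trial table is missing required column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  bad_grp <- setdiff(unique(trials$group), group_levels)
  if (length(bad_grp)) {
    abort(paste0("Unknown group label(s): ", paste(bad_grp, collapse = ", "),
                 " (expected ", paste(group_levels, collapse = ", "), ")."))
  }
  if (require_correct && !all(trials$correct %in% c(0, 1))) {
    abort("`correct` must be 0 or 1 for every trial.")
  }
  cond <- unique(as.character(trials$condition))
  bad <- cond[cond != "baseline" & is.na(suppressWarnings(as.numeric(cond)))]
  if (length(bad)) {
    abort(paste0("Unknown condition token(s): ", paste(bad, collapse = ", "),
                 " (expected a numeric flanker distance or 'baseline')."))
  }
  invisible(trials)
}

#' Build the model design bundle from a trial table
#'
#' Assembles the fixed-effect matrix, the per-observer random-effect matrix
#' (columns: intercept, contrast), the observer grouping index and the
#' response from trial-level data. Two observation codings are supported and
#' give identical likelihoods: `"binomial"` aggregates trials into
#' (observer, condition, contrast) cells with success counts — the
#' "probability of being correct out of the total number of trials" view —
#' while `"bernoulli"` keeps one row per trial.
#'
#' @param trials Trial tibble with columns `observer_id`, `group`,
#'   `condition`, `contrast`, `correct`.
#' @param spec A [model_spec()].
#' @param coding `"binomial"` (default) or `"bernoulli"`.
#' @return A list of class `lm_design`: `X`, `Z`, `obs_index` (0-based,
#'   contiguous), `y`, `n`, `terms`, `observers`, `coding`, `spec`.
#' @export
build_design <- function(trials, spec = model_spec("baseline"),
                         coding = c("binomial", "bernoulli")) {
  coding <- match.arg(coding)
  stopifnot(inherits(spec, "lm_model_spec"))
  validate_trials(trials)
  if (spec$model == "flanker") {
    if (any(trials$condition == "baseline")) {
      abort(paste0("The flanker model has no distance coordinate for the ",
                   "baseline block; fit it to flanker trials only ",
                   "(filter out condition == 'baseline')."))
    }
  }
  if (length(unique(trials$group)) < 2) {
    abort(paste0("Single-group data cannot identify the group terms of the '",
                 spec$model, "' model; supply both groups."))
  }
  if (coding == "binomial") {
    cells <- trials |>
      dplyr::summarise(y = sum(.data$correct), n = dplyr::n(),
                       .by = c("observer_id", "group", "condition", "contrast"))
  } else {
    cells <- trials |>
      dplyr::mutate(y = .data$correct, n = 1L) |>
      dplyr::select("observer_id", "group", "condition", "contrast", "y", "n")
  }
  cells <- dplyr::arrange(cells, .data$observer_id, .data$condition,
                          .data$contrast)
  g <- as.numeric(cells$group == "migraine_aura")
  ct <- cells$contrast
  cols <- list(
    "(Intercept)" = rep(1, nrow(cells)),
    "contrast" = ct,
    "group" = g,
    "group:contrast" = g * ct
  )
  if (spec$model == "flanker") {
    d <- as.numeric(as.character(cells$condition))
    cols <- c(cols, list(
      "distance" = d,
      "contrast:distance" = ct * d,
      "group:distance" = g * d,
      "group:distance:contrast" = g * d * ct
    ))
  }
  X <- do.call(cbind, cols[spec$fixed_terms])
  colnames(X) <- spec$fixed_terms
  observers <- unique(cells$observer_id)
  structure(
    list(
      X = X,
      Z = cbind(intercept = rep(1, nrow(cells)), contrast = ct),
      obs_index = match(cells$observer_id, observers) - 1L,
      y = as.numeric(cells$y),
      n = as.numeric(cells$n),
      terms = spec$fixed_terms,
      observers = observers,
      groups = cells$group[match(observers, cells$observer_id)],
      coding = coding,
      spec = spec
    ),
    class = "lm_design"
  )
}
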