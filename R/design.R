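#' Session design for a 2AFC lateral-masking experiment
#'
#' Describes one observer's testing session: the set of target Michelson
#' contrasts, the number of repetitions of each contrast within a block, and
#' the block structure (one block per collinear-flanker distance, plus an
#' optional no-flanker baseline block). The default reproduces the classic
#' design this package targets: seven contrast levels between 0.0075 and 0.09,
#' 20 repetitions per level (140 trials per block), six flanker distances
#' of 1, 2, 3, 4, 6 and 12 Gabor wavelengths, and a baseline block —
#' seven blocks and 980 trials per observer in total.
#'
#' @param contrast_levels Numeric vector of Michelson-contrast proportions in
#'   (0, 1], strictly increasing.
#' @param reps_per_level Number of repetitions of each contrast level within a
#'   block (>= 1).
#' @param flanker_distances Centre-to-centre target-flanker distances in units
#'   of the Gabor wavelength (lambda); strictly positive.
#' @param include_baseline Include a no-flanker baseline block?
#' @param n_intervals Number of intervals per forced-choice trial (2 for 2AFC;
#'   informational, chance level is `1/n_intervals`).
#'
#' @return An object of class `session_design` (a list with the validated
#'   fields plus the derived condition set).
#' @examples
#' d <- session_design()
#' trials_per_block(d)   # 140
#' n_blocks(d)           # 7
#' @export
session_design <- function(contrast_levels = c(0.0075, 0.015, 0.0225, 0.03,
                                               0.045, 0.06, 0.09),
                           reps_per_level = 20,
                           flanker_distances = c(1, 2, 3, 4, 6, 12),
                           include_baseline = TRUE,
                           n_intervals = 2) {
  if (!is.numeric(contrast_levels) || length(contrast_levels) == 0) {
    abort("`contrast_levels` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(contrast_levels)) ||
      any(contrast_levels <= 0) || any(contrast_levels > 1)) {
    abort("All contrast levels must be finite Michelson proportions in (0, 1].")
  }
  if (is.unsorted(contrast_levels, strictly = TRUE)) {
    abort("`contrast_levels` must be strictly increasing with no duplicates.")
  }
  if (!is.numeric(reps_per_level) || length(reps_per_level) != 1 ||
      reps_per_level < 1 || reps_per_level != round(reps_per_level)) {
    abort("`reps_per_level` must be a single integer >= 1.")
  }
  if (length(flanker_distances) > 0 &&
      (any(!is.finite(flanker_distances)) || any(flanker_distances <= 0))) {
    abort("`flanker_distances` must all be strictly positive.")
  }
  if (anyDuplicated(flanker_distances)) {
    abort("`flanker_distances` must not contain duplicates.")
  }
  if (!isTRUE(include_baseline) && !isFALSE(include_baseline)) {
    abort("`include_baseline` must be TRUE or FALSE.")
  }
  conditions <- as.character(flanker_distances)
  if (include_baseline) conditions <- c(conditions, "baseline")
  if (length(conditions) == 0) {
    abort("The design must contain at least one condition block.")
  }
  structure(
    list(
      contrast_levels = as.numeric(contrast_levels),
      reps_per_level = as.integer(reps_per_level),
      flanker_distances = as.numeric(flanker_distances),
      include_baseline = include_baseline,
      n_intervals = as.integer(n_intervals),
      conditions = conditions
    ),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat("<session_design>\n")
  cat("  contrast levels :", paste(x$contrast_levels, collapse = ", "), "\n")
  cat("  reps per level  :", x$reps_per_level, "\n")
  cat("  flanker blocks  :", paste(x$flanker_distances, collapse = ", "),
      "lambda\n")
  cat("  baseline block  :", x$include_baseline, "\n")
  cat("  trials per block:", trials_per_block(x), "\n")
  cat("  blocks          :", n_blocks(x), "\n")
  invisible(x)
}

#' Design arithmetic
#'
#' `trials_per_block()` is levels x repetitions; `n_blocks()` counts flanker
#' distances plus the baseline; `trials_per_observer()` is their product.
#'
#' @param design A [session_design()].
#' @return A single integer count.
#' @export
trials_per_block <- function(design) {
  stopifnot(inherits(design, "session_design"))
  length(design$contrast_levels) * design$reps_per_level
}

#' @rdname trials_per_block
#' @export
n_blocks <- function(design) {
  stopifnot(inherits(design, "session_design"))
  length(design$conditions)
}

#' @rdname trials_per_block
#' @export
trials_per_observer <- function(design) {
  trials_per_block(design) * n_blocks(design)
}
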