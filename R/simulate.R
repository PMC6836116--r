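#' Simulate one block of 2AFC trials for a single observer
#'
#' For each contrast level `c` in the design, draws `reps_per_level` Bernoulli
#' outcomes with success probability `pnorm(intercept + slope * c +
#' intercept_offset)` and randomises the trial order within the block, as the
#' experimental procedure randomised contrast levels within each block.
#'
#' @param obs One observer: a one-row data frame (or list) with fields
#'   `observer_id`, `group`, `intercept`, `contrast_slope` — one row of
#'   [draw_observers()].
#' @param design A [session_design()].
#' @param condition Condition token for this block: a flanker distance from
#'   the design (e.g. `"3"` or `3`) or `"baseline"`.
#' @param seed Integer seed for this block's stream.
#' @param intercept_offset Additive probit offset for this condition (used by
#'   [simulate_dataset()] to realise per-condition facilitation scenarios).
#'
#' @return A tibble of trial records: `observer_id`, `group`, `condition`,
#'   `contrast`, `correct` (0/1), in randomised presentation order.
#' @export
simulate_trials <- function(obs, design, condition, seed = 1L,
                            intercept_offset = 0) {
  stopifnot(inherits(design, "session_design"))
  obs <- as.list(obs)
  condition <- as.character(condition)
  if (!condition %in% design$conditions) {
    abort(paste0("Condition '", condition,
                 "' is not part of the session design (",
                 paste(design$conditions, collapse = ", "), ")."))
  }
  eta <- obs$intercept + obs$contrast_slope * design$contrast_levels +
    intercept_offset
  if (any(!is.finite(eta))) {
    abort("Non-finite linear predictor: check observer intercept/slope.")
  }
  p <- pnorm(eta)
  reps <- design$reps_per_level
  withr_seed(seed, {
    correct <- rbinom(length(p) * reps, 1L,
                      rep(p, each = reps))
    ord <- sample.int(length(correct))
    tibble::tibble(
      observer_id = obs$observer_id,
      group = obs$group,
      condition = condition,
      contrast = rep(design$contrast_levels, each = reps)[ord],
      correct = correct[ord]
    )
  })
}

#' Simulate a complete multi-observer lateral-masking dataset
#'
#' Draws a population of observers and simulates every observer through every
#' condition block of the design (by default six flanker-distance blocks plus
#' the no-flanker baseline). Per-(observer, block) random streams are derived
#' from the master seed with a splittable counter scheme, so the full table is
#' bit-reproducible and any observer/block subset can be regenerated in
#' isolation.
#'
#' @param pop A [population_params()]; its optional `condition_effects` add a
#'   probit intercept offset within the named condition blocks.
#' @param design A [session_design()].
#' @param seed Master integer seed.
#' @param observers Optional pre-drawn observer table (as from
#'   [draw_observers()]); by default observers are drawn from `pop` using a
#'   stream derived from `seed`.
#'
#' @return A trial tibble with `observers x blocks x levels x reps` rows and
#'   columns `observer_id`, `group`, `condition`, `contrast`, `correct`.
#' @examples
#' pop <- population_params(group_sizes = c(control = 2, migraine_aura = 2))
#' trials <- simulate_dataset(pop, session_design(), seed = 7)
#' nrow(trials) # 4 * 7 * 140
#' @export
simulate_dataset <- function(pop, design = session_design(), seed = 1L,
                             observers = NULL) {
  stopifnot(inherits(pop, "population_params"), inherits(design, "session_design"))
  if (is.null(observers)) {
    observers <- draw_observers(pop, seed = derive_seed(seed, 0L))
  }
  offsets <- setNames(numeric(length(design$conditions)), design$conditions)
  if (!is.null(pop$condition_effects)) {
    extra <- setdiff(names(pop$condition_effects), design$conditions)
    if (length(extra)) {
      abort(paste0("condition_effects name conditions not in the design: ",
                   paste(extra, collapse = ", ")))
    }
    offsets[names(pop$condition_effects)] <- pop$condition_effects
  }
  blocks <- tidyr::expand_grid(i = seq_len(nrow(observers)),
                               condition = design$conditions)
  purrr::pmap(blocks, function(i, condition) {
    simulate_trials(observers[i, ], design, condition,
                    seed = derive_seed(seed, i, match(condition, design$conditions)),
                    intercept_offset = offsets[[condition]])
  }) |>
    purrr::list_rbind()
}
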