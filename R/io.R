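#' Read and write trial tables
#'
#' Trial tables are plain CSV with a header row and required columns
#' `observer_id`, `group`, `condition`, `contrast`, `correct`; `condition`
#' is an integer wavelength distance or the literal token `"baseline"`.
#' Unknown extra columns are preserved. Malformed rows (a `correct` value
#' outside \{0, 1\}, a non-numeric contrast) are rejected with their row
#' numbers.
#'
#' @param path File path.
#' @return `read_trials()` returns a trial tibble; `write_trials()` returns
#'   `path` invisibly. A write/read round trip is lossless.
#' @export
read_trials <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  required <- c("observer_id", "group", "condition", "contrast", "correct")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(paste0("Trial file is missing required column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  tbl$observer_id <- as.character(tbl$observer_id)
  tbl$condition <- as.character(tbl$condition)
  if (nrow(tbl) == 0) return(tbl)
  bad <- which(!tbl$correct %in% c(0, 1) |
                 !is.finite(suppressWarnings(as.numeric(tbl$contrast))))
  if (length(bad)) {
    abort(paste0("Malformed trial row(s) at: ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..." else "",
                 " (`correct` must be 0/1, `contrast` numeric)."))
  }
  tbl$correct <- as.integer(tbl$correct)
  validate_trials(tbl)
  tbl
}

#' @rdname read_trials
#' @param trials A trial tibble.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path)
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` (e.g.
#'   `"clinical_table1.csv"`); `NULL` lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
latmask_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "latmask"))
  } else {
    f <- system.file("extdata", file, package = "latmask")
    if (f == "") abort(paste0("No packaged file named '", file, "'."))
    f
  }
}

#' Read the clinical-features table
#'
#' Parses a CSV transcription of the migraine observers' clinical features
#' (id, sex, age, age of onset, time since prior attack, attack-frequency
#' category, exclusion flag). The token `NDI` (non-disclosed information)
#' is parsed as missing, never as zero.
#'
#' @param path CSV path; defaults to the packaged transcription.
#' @return A tibble with `observer`, `sex`, `age`, `age_started`,
#'   `prior_attack`, `frequency_per_month`, `excluded`.
#' @export
read_clinical <- function(path = latmask_example("clinical_table1.csv")) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           observer = readr::col_character(),
                           sex = readr::col_character(),
                           age = readr::col_double(),
                           age_started = readr::col_character(),
                           prior_attack = readr::col_character(),
                           frequency_per_month = readr::col_character(),
                           excluded = readr::col_logical()
                         ))
  ndi_na <- function(x) ifelse(x == "NDI", NA_character_, x)
  tbl$age_started <- suppressWarnings(as.numeric(ndi_na(tbl$age_started)))
  tbl$frequency_per_month <- ndi_na(tbl$frequency_per_month)
  tbl
}

#' Tally the clinical table
#'
#' Counts included observers (exclusion flag honoured) and the female/male
#' split among the included rows.
#'
#' @param clinical A tibble from [read_clinical()].
#' @return A one-row tibble: `n_included`, `n_female`, `n_male`.
#' @export
tally_clinical <- function(clinical) {
  bad <- setdiff(unique(clinical$sex), c("F", "M"))
  if (length(bad)) {
    abort(paste0("Unknown sex token(s): ", paste(bad, collapse = ", "),
                 " (expected F or M)."))
  }
  inc <- clinical[!clinical$excluded, , drop = FALSE]
  tibble::tibble(
    n_included = nrow(inc),
    n_female = sum(inc$sex == "F"),
    n_male = sum(inc$sex == "M")
  )
}

#' Serialize a fitted model or bootstrap summary as JSON
#'
#' The fit JSON records estimates, standard errors, t statistics, degrees of
#' freedom, p values, the random-effects covariance and the log-likelihood;
#' the bootstrap JSON records the seed, sample counts, covariance mode and
#' per-group SDs. Both embed the digest of any run configuration supplied.
#'
#' @param fit A [fit_probit_glmm()] result.
#' @param path Output path.
#' @param config Optional [run_config()] whose hash is embedded.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, config = NULL) {
  stopifnot(inherits(fit, "probit_glmm"))
  out <- list(
    model = fit$spec$model, link = fit$spec$link, nAGQ = fit$nAGQ,
    coefficients = wald_report(fit),
    sigma_re = unclass(fit$sigma_re_hat),
    loglik = fit$loglik, n_obs = fit$n_obs,
    n_observers = fit$n_observers,
    converged = fit$converged, n_iter = fit$n_iter
  )
  if (!is.null(config)) out$config_hash <- config_hash(config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_fit_json
#' @param boot A [bootstrap_threshold_sd()] summary.
#' @export
write_bootstrap_json <- function(boot, path, config = NULL) {
  stopifnot(inherits(boot, "threshold_bootstrap"))
  out <- list(
    seed = boot$seed, n_requested = boot$n_requested,
    n_samples = boot$n_samples, n_dropped = boot$n_dropped,
    covariance = boot$covariance, criterion = boot$criterion,
    sd = as.list(boot$sd),
    observed = boot$observed
  )
  if (!is.null(config)) out$config_hash <- config_hash(config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Run configuration
#'
#' Bundles every knob of a simulation-plus-analysis run — design,
#' generative population, fit options and bootstrap options — into one
#' serializable object, so a run is reproducible from its configuration and
#' seed alone. `config_hash()` gives a short digest that output writers
#' embed, and `write_config()`/`read_config()` round-trip the configuration
#' through JSON.
#'
#' @param design A [session_design()].
#' @param population A [population_params()].
#' @param fit Fit options: `nAGQ`, `coding`.
#' @param bootstrap Bootstrap options: `n_samples`, `covariance`, `nAGQ`.
#' @param seed Master seed.
#' @return An object of class `lm_run_config`.
#' @export
run_config <- function(design = session_design(),
                       population = population_params(),
                       fit = list(nAGQ = 7, coding = "binomial"),
                       bootstrap = list(n_samples = 1000,
                                        covariance = "ranef", nAGQ = 1),
                       seed = 1L) {
  stopifnot(inherits(design, "session_design"),
            inherits(population, "population_params"))
  # canonicalize count-valued options so a JSON round trip hashes identically
  for (f in intersect(names(fit), "nAGQ")) fit[[f]] <- as.integer(fit[[f]])
  for (f in intersect(names(bootstrap), c("n_samples", "nAGQ"))) {
    bootstrap[[f]] <- as.integer(bootstrap[[f]])
  }
  structure(
    list(design = unclass(design), population = unclass(population),
         fit = fit, bootstrap = bootstrap, seed = as.integer(seed)),
    class = "lm_run_config"
  )
}

#' @rdname run_config
#' @param config An `lm_run_config`.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' @rdname run_config
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "lm_run_config"))
  out <- unclass(config)
  # keep the condition -> offset map as a JSON object (names survive)
  if (!is.null(out$population$condition_effects)) {
    out$population$condition_effects <-
      as.list(out$population$condition_effects)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # names of length-1 maps are lost under simplification; re-read unsimplified
  raw$population$condition_effects <-
    jsonlite::read_json(path)$population$condition_effects
  run_config(
    design = do.call(session_design,
                     raw$design[c("contrast_levels", "reps_per_level",
                                  "flanker_distances", "include_baseline",
                                  "n_intervals")]),
    population = population_params(
      beta = raw$population$beta,
      sigma_re = matrix(unlist(raw$population$sigma_re), 2, 2),
      group_sizes = unlist(raw$population$group_sizes),
      condition_effects = {
        ce <- raw$population$condition_effects
        if (is.null(ce) || length(ce) == 0) NULL else unlist(ce)
      }
    ),
    fit = raw$fit, bootstrap = raw$bootstrap, seed = raw$seed
  )
}
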