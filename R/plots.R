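#' Plot group thresholds with bootstrap uncertainty
#'
#' Group 75% thresholds from the original fit with error bars of plus/minus
#' one bootstrap standard deviation.
#'
#' @param object,x A [bootstrap_threshold_sd()] summary.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_bootstrap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$observed)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$observed - .data$sd,
                   ymax = .data$observed + .data$sd),
      width = 0.15) +
    ggplot2::labs(x = NULL,
                  y = sprintf("Contrast threshold (%.0f%% correct)",
                              100 * object$criterion)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.threshold_bootstrap
#' @export
plot.threshold_bootstrap <- function(x, ...) print(autoplot(x, ...))

#' Plot fitted psychometric functions over the observed data
#'
#' Group-level fitted probit curves together with per-observer proportions
#' correct at each contrast level.
#'
#' @param fit A baseline-model [fit_probit_glmm()] result.
#' @param n_curve Number of contrast points for the fitted curves.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(fit, n_curve = 200) {
  stopifnot(inherits(fit, "probit_glmm"))
  if (fit$spec$model != "baseline") {
    abort("plot_psychometric() displays baseline-model fits.")
  }
  des <- fit$design
  pts <- tibble::tibble(
    observer = des$observers[des$obs_index + 1],
    group = des$groups[des$obs_index + 1],
    contrast = des$X[, "contrast"],
    prop = des$y / des$n
  )
  cs <- seq(0, max(pts$contrast), length.out = n_curve)
  curves <- purrr::map(group_levels, function(g) {
    tibble::tibble(group = g, contrast = cs,
                   p = predict_p(fit, cs, group = g))
  }) |> purrr::list_rbind()
  ggplot2::ggplot(curves, ggplot2::aes(.data$contrast, .data$p,
                                       colour = .data$group)) +
    ggplot2::geom_jitter(data = pts,
                         ggplot2::aes(y = .data$prop), alpha = 0.25,
                         width = 0, height = 0.01, size = 0.8) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "Michelson contrast", y = "P(correct)",
                  colour = "Group") +
    ggplot2::theme_minimal()
}
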