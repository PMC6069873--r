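# Plots: per-fit scatter of instrument effects with the fitted line, and a
# forest-style comparison of estimators across pairs.

#' Scatter plot of an MR fit
#'
#' Instrument exposure effects against outcome effects (MR-Egger
#' orientation, `beta_x >= 0`), with the fitted line: through the origin
#' for IVW and the weighted median, with the estimated intercept for
#' MR-Egger.  Point size scales with the inverse-variance weight.
#'
#' @param object An `mr_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  h <- object$data
  if (is.null(h)) abort("fit carries no instrument data to plot")
  flip <- h$beta_x < 0
  df <- tibble::tibble(
    beta_x = ifelse(flip, -h$beta_x, h$beta_x),
    beta_y = ifelse(flip, -h$beta_y, h$beta_y),
    weight = h$beta_x^2 / h$se_y^2
  )
  intercept <- object$intercept %||% 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), alpha = 0.6) +
    ggplot2::geom_abline(intercept = intercept, slope = object$beta,
                         colour = "steelblue") +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(
      x = "SNP effect on exposure (SD/allele)",
      y = "SNP effect on outcome (SD/allele)",
      title = sprintf("%s: %.3g (95%% CI %.3g to %.3g)",
                      object$estimator, object$beta, object$ci_low,
                      object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of MR estimates
#'
#' Point estimates with 95% confidence intervals for every estimator and
#' exposure-outcome pair in a long results tibble.
#'
#' @param results Long results tibble from [mr_pair()]/[run_analysis()].
#' @return A ggplot.
#' @export
plot_mr_forest <- function(results) {
  if (!"analysis" %in% names(results)) results$analysis <- "main"
  df <- dplyr::mutate(results,
                      pair = paste(.data$exposure, .data$outcome,
                                   sep = " → "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$pair,
                                   colour = .data$estimator)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~analysis) +
    ggplot2::labs(x = "Causal estimate (outcome SD per exposure SD)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
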