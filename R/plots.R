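#' Bland-Altman plot for a validation report
#'
#' Differences (estimated - true METs) against pair means, with the bias
#' (solid) and 95% limits of agreement (dashed).
#'
#' @param report A `met_validation` object.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(report) {
  stopifnot(inherits(report, "met_validation"))
  df <- report$predictions |>
    dplyr::mutate(mean_met = (.data$true_met + .data$estimated_met) / 2,
                  diff_met = .data$estimated_met - .data$true_met)
  ba <- report$bland_altman
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_met, y = .data$diff_met)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = ba$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of true and estimated METs",
      y = "Estimated - true METs",
      title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f]",
                      ba$bias, ba$loa_low, ba$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' ROC curves for a validation report
#'
#' Empirical ROC curves for the SED, MVPA and VPA tasks, using the estimated
#' MET as score (negated for SED).
#'
#' @param report A `met_validation` object.
#' @return A ggplot object.
#' @export
plot_roc <- function(report) {
  stopifnot(inherits(report, "met_validation"))
  pred <- report$predictions
  curves <- purrr::map_dfr(c("SED", "MVPA", "VPA"), function(task) {
    truth <- binarize_by_category(pred$true_met, task)
    score <- if (task == "SED") -pred$estimated_met else pred$estimated_met
    roc <- pROC::roc(response = truth, predictor = score,
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    tibble::tibble(
      category = task,
      fpr = rev(1 - roc$specificities),
      tpr = rev(roc$sensitivities)
    )
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               color = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey50") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", color = NULL,
                  title = "ROC curves by intensity task") +
    ggplot2::theme_minimal()
}

#' Correlation plot of estimated against true METs
#'
#' @param report A `met_validation` object.
#' @return A ggplot object.
#' @export
plot_met_scatter <- function(report) {
  stopifnot(inherits(report, "met_validation"))
  ggplot2::ggplot(report$predictions,
                  ggplot2::aes(x = .data$true_met, y = .data$estimated_met)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(
      x = "True METs (criterion)", y = "Estimated METs",
      title = sprintf("Spearman rho = %.2f, ICC = %.2f",
                      report$spearman$rho, report$icc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.met_validation <- function(object, type = c("bland_altman", "roc",
                                                     "scatter"), ...) {
  switch(match.arg(type),
         bland_altman = plot_bland_altman(object),
         roc = plot_roc(object),
         scatter = plot_met_scatter(object))
}
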