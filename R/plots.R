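#' @describeIn run_gwa Quantile-quantile plot of the scan's p-values.
#' @param object A `gwa_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.gwa_result <- function(object, ...) {
  qq <- qq_data(object)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$report_threshold),
                        colour = "firebrick", linetype = 3) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = sprintf("QQ plot (%d variants, sex mode '%s')",
                      nrow(object$records), object$sex_mode)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_anova Bar chart of the estimated variance components.
#' @param object A `lead_varcomp`.
#' @exportS3Method ggplot2::autoplot
autoplot.lead_varcomp <- function(object, ...) {
  vc <- object$varcomp
  vc$term <- factor(vc$term, levels = vc$term)
  ggplot2::ggplot(vc, ggplot2::aes(x = .data$term, y = .data$variance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "variance component",
                  title = sprintf("Variance partition: %s (%s model, %s)",
                                  object$trait, object$model,
                                  toupper(object$method))) +
    ggplot2::theme_minimal()
}

#' Reaction-norm plot of per-line lead sensitivity
#'
#' Lines ordered by sensitivity, with control and lead cell means joined by
#' a segment whose length is the sensitivity phenotype.
#'
#' @param sens A [sensitivity()] tibble.
#' @param sex Optional sex filter for sexed traits.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sens, sex = NULL) {
  if (!is.null(sex) && "sex" %in% names(sens)) {
    sens <- dplyr::filter(sens, .data$sex == !!sex)
  }
  d <- sens %>%
    dplyr::filter(!is.na(.data$sensitivity)) %>%
    dplyr::arrange(.data$sensitivity) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    tidyr::pivot_longer(c("mean_control", "mean_lead"),
                        names_to = "treatment", values_to = "mean",
                        names_prefix = "mean_")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$mean)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$rank), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$treatment), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(control = "firebrick", lead = "steelblue")) +
    ggplot2::labs(x = "line (ordered by sensitivity)", y = "cell mean",
                  colour = "medium") +
    ggplot2::theme_minimal()
}

#' Bar plot of mutant sensitivity statistics
#'
#' One bar per mutant (and sex), height the difference-of-differences
#' sensitivity statistic, error bars the combined SEM, filled when the
#' line-by-treatment interaction is significant at 0.05.
#'
#' @param results Row-bound [fit_mutant_anova()] results.
#' @return A ggplot object.
#' @export
plot_mutant_sensitivity <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$mutant, y = .data$sensitivity,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sensitivity - .data$sem_combined,
                                        ymax = .data$sensitivity + .data$sem_combined),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "white"),
                               guide = "none") +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = NULL, y = "sensitivity (lead[m - c] - regular[m - c])") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
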