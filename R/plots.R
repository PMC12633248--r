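#' Plot band-wise group effect sizes
#'
#' Cohen's d per frequency band with Hedges-Olkin 95% CIs, faceted by
#' metric; cells surviving FDR (q < 0.05) are highlighted.
#'
#' @param object A `band_contrasts` table.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.band_contrasts <- function(object, ...) {
  df <- dplyr::filter(object, .data$band != "broadband")
  df$band <- factor(df$band, levels = make_bands()$band)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$d,
                                   colour = .data$q_value < 0.05)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$d_low,
                                          ymax = .data$d_high)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#c0392b"),
                                 name = "q < 0.05") +
    ggplot2::labs(x = "frequency band (Hz)", y = "Cohen's d (HC - MDD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an ROC curve
#'
#' @param object An `eval_report` from [evaluate_scores()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a DFA fluctuation function
#'
#' Log-log fluctuation `F(s)` against window length with the fitted
#' power-law slope.
#'
#' @param object A `dfa_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dfa_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "#2980b9") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window length s (s)", y = "F(s)",
                  title = sprintf("DFA exponent = %.3f", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot the LASSO coefficient path
#'
#' @param classifier A `group_classifier`.
#' @return A ggplot of coefficient trajectories over the lambda grid with
#'   the selected lambda marked.
#' @export
plot_lasso_path <- function(classifier) {
  fit <- classifier$model$fit
  B <- as.matrix(fit$beta)
  df <- tibble::tibble(
    feature = rep(rownames(B), ncol(B)),
    lambda = rep(fit$lambda, each = nrow(B)),
    weight = as.numeric(B))
  df <- dplyr::filter(df, .data$feature %in%
                        df$feature[df$weight != 0])
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$weight,
                                   group = .data$feature)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = classifier$lambda, linetype = 2,
                        colour = "#c0392b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "coefficient") +
    ggplot2::theme_minimal()
}
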