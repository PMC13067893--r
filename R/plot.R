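#' Text label for an AUC result
#'
#' Mirrors the in-text reporting style: `"AUC = 0.731 (95% CI: 0.630-0.833)"`
#' with three-decimal half-up rounding; missing bounds render as `NA`.
#'
#' @param auc_result A `dx_auc_ci` object from [dx_delong()].
#' @return A single string.
#' @export
dx_auc_label <- function(auc_result) {
  sprintf("AUC = %s (95%% CI: %s–%s)", dx_round(auc_result$auc),
          dx_round(auc_result$lower), dx_round(auc_result$upper))
}

#' ROC plot with confidence band, optimal cutoff and AUC label
#'
#' Draws the ROC curve with the x-axis showing specificity in reversed
#' direction (equivalent to 1 - specificity), the chance diagonal, an
#' optional shaded bootstrap sensitivity band, an optional annotated
#' optimal-cutoff marker, and the AUC with its 95% CI as a label.
#'
#' @param curve A `dx_roc` object.
#' @param auc_result A `dx_auc_ci` object.
#' @param band Optional `dx_band` object from [dx_bootstrap_band()].
#' @param cutoff Optional `dx_cutoff` object from [dx_optimal_cutoff()].
#' @param path Optional output path; when supplied the plot is also saved
#'   (PNG at 300 dpi by default; format follows the file extension).
#' @param width,height,dpi Device size in inches and resolution used when
#'   saving.
#' @return The ggplot object, invisibly.
#' @export
dx_plot_roc <- function(curve, auc_result, band = NULL, cutoff = NULL,
                        path = NULL, width = 6, height = 6, dpi = 300) {
  stopifnot(inherits(curve, "dx_roc"), inherits(auc_result, "dx_auc_ci"))
  df <- as.data.frame(curve)
  df <- df[order(-df$specificity, df$sensitivity), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$specificity,
                                        y = .data$sensitivity))
  if (!is.null(band)) {
    p <- p + ggplot2::geom_ribbon(
      data = as.data.frame(band),
      ggplot2::aes(x = .data$specificity, ymin = .data$se_lower,
                   ymax = .data$se_upper),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.25
    )
  }
  p <- p +
    ggplot2::geom_abline(intercept = 1, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, colour = "steelblue4") +
    ggplot2::scale_x_reverse(limits = c(1, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Specificity", y = "Sensitivity") +
    ggplot2::annotate("text", x = 0.05, y = 0.05, hjust = 1, vjust = 0,
                      label = dx_auc_label(auc_result), size = 3.6) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    lab <- sprintf("%s (Se = %s, Sp = %s)", dx_round(cutoff$threshold),
                   dx_round(cutoff$sensitivity),
                   dx_round(cutoff$specificity))
    p <- p +
      ggplot2::annotate("point", x = cutoff$specificity,
                        y = cutoff$sensitivity, colour = "firebrick",
                        size = 2.5) +
      ggplot2::annotate("text", x = cutoff$specificity,
                        y = cutoff$sensitivity, label = lab,
                        hjust = -0.05, vjust = 1.4, size = 3.2,
                        colour = "firebrick")
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, plot = p, width = width, height = height,
                    dpi = dpi)
  }
  invisible(p)
}
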