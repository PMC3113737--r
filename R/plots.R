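#' Plot a propensity table
#'
#' Bar chart of per-amino-acid propensities with bootstrap error bars
#' and a reference line at 1 (no enrichment).
#'
#' @param object A `propensity_table` from [propensity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot propensity_table
#' @export
autoplot.propensity_table <- function(object, ...) {
  d <- filter(as_tibble(object), is.finite(.data$propensity))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$aa, y = .data$propensity)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "amino acid", y = "binding propensity P(i)",
      title = sprintf("%s, %s channel",
                      attr(object, "ligand_het") %||% "ligand",
                      attr(object, "channel") %||% "overall")) +
    ggplot2::theme_minimal()
  if (any(is.finite(d$err))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$propensity - .data$err,
                   ymax = .data$propensity + .data$err), width = 0.3)
  }
  p
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Plot a ROC curve
#'
#' @param object A `roc_curve` tibble from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object with the chance diagonal for reference.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Heatmap of a cross-prediction matrix
#'
#' @param cp Long-format tibble from [cross_predict()].
#' @return A ggplot tile plot, rows = trained ligand, columns = tested
#'   ligand, fill = AUC in percent.
#' @export
plot_cross_prediction <- function(cp) {
  ggplot2::ggplot(cp, ggplot2::aes(x = .data$tested, y = .data$trained,
                                   fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$auc)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "AUC (%)") +
    ggplot2::labs(x = "tested ligand", y = "trained ligand") +
    ggplot2::theme_minimal()
}
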