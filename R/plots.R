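# ggplot2 views of each result type. All plotters take the tibble a
# pipeline stage returns and give back a ggplot object the caller can
# restyle.

#' Bar plot of per-family inosine fold changes
#'
#' @param fc Fold-change table from [inosine_fold_change()].
#' @return A ggplot: log2 fold change in I-to-A ratio per tRNA family.
#' @export
plot_inosine_fold_change <- function(fc) {
  ggplot2::ggplot(fc, ggplot2::aes(
    x = stats::reorder(.data$family_id, -.data$log2_fold_change),
    y = .data$log2_fold_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "tRNA family",
                  y = "log2 fold change, I-to-A ratio (case / control)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Ranked fold-enrichment plot of codon-bias scores
#'
#' @param bias Bias table from [codon_bias()].
#' @param threshold Cutoff line (defaults to the table's recorded
#'   threshold, else 1.5).
#' @return A ggplot of per-gene fold enrichment on a log2 y axis.
#' @export
plot_bias_scores <- function(bias, threshold = NULL) {
  threshold <- threshold %||% attr(bias, "threshold") %||% 1.5
  df <- dplyr::arrange(bias, dplyr::desc(.data$fold_enrichment))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$fold_enrichment,
                                   colour = .data$fold_enrichment > threshold)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50"),
                                 name = paste0("> ", threshold, "-fold")) +
    ggplot2::labs(x = "gene rank", y = "dependent-codon fold enrichment") +
    ggplot2::theme_minimal()
}

#' Concordance scatter of translation-efficiency fold changes
#'
#' Overexpression TE response against knockout TE response; concordant
#' genes (up under overexpression, down under knockout, with Ribo-seq
#' agreeing) sit in the lower-right quadrant.
#'
#' @param te Table from [translation_efficiency()].
#' @return A ggplot.
#' @export
plot_te_concordance <- function(te) {
  ggplot2::ggplot(te, ggplot2::aes(x = .data$log2fc_te_oe,
                                   y = .data$log2fc_te_ko,
                                   colour = .data$concordant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 FC TE (ADAT2 OE / control)",
                  y = "log2 FC TE (ADAT2 KO / control)",
                  colour = "concordant") +
    ggplot2::theme_minimal()
}

#' Funnel plot of stage sizes
#'
#' @param object An `adat_funnel` from [run_funnel()].
#' @param ... Unused.
#' @return A ggplot bar chart of genes surviving each stage.
#' @method autoplot adat_funnel
#' @export
autoplot.adat_funnel <- function(object, ...) {
  df <- tibble(
    stage = factor(c("concordant\nTE + Ribo", "codon bias",
                     "tumor\noverexpressed"),
                   levels = c("concordant\nTE + Ribo", "codon bias",
                              "tumor\noverexpressed")),
    n = c(length(object$stage1), length(object$stage2),
          length(object$stage3))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "genes remaining") +
    ggplot2::theme_minimal()
}
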