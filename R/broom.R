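#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-gene evidence of a funnel result
#'
#' @param x An `adat_funnel` from [run_funnel()].
#' @param ... Unused.
#' @return One row per gene in the shared universe with concordance, bias
#'   and (when available) tumor evidence plus `stage_reached` (0-3).
#' @method tidy adat_funnel
#' @export
tidy.adat_funnel <- function(x, ...) {
  dplyr::arrange(x$evidence, dplyr::desc(.data$stage_reached), .data$gene_id)
}

#' One-row summary of a funnel result
#'
#' @param x An `adat_funnel` from [run_funnel()].
#' @param ... Unused.
#' @return A tibble with stage sizes, the bias threshold, the scored codon
#'   subset and whether the tumor filter ran.
#' @method glance adat_funnel
#' @export
glance.adat_funnel <- function(x, ...) {
  tibble(
    n_stage1 = length(x$stage1),
    n_stage2 = length(x$stage2),
    n_stage3 = length(x$stage3),
    n_dropped = nrow(x$dropped),
    bias_threshold = x$config$bias_threshold,
    codon_subset = paste(x$config$codon_subset, collapse = ","),
    tumor_filter_applied = x$tumor_filter_applied
  )
}
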