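# The three-stage candidate funnel: TE/Ribo concordance -> A-to-I codon
# usage bias -> tumor overexpression, with per-gene evidence and
# deterministic ranking.

#' Configuration for the candidate funnel
#'
#' @param bias_threshold Fold-enrichment cutoff for the codon-bias stage
#'   (default 1.5, the screen's published cutoff). Must be positive.
#' @param codon_subset Dependent codons scored at the bias stage; defaults
#'   to `c("TCC", "CTC", "CGC")`, the codons read by the three tRNA
#'   families whose inosine levels respond most strongly to ADAT2.
#' @param oe_alpha BH-adjusted q-value cutoff for the tumor overexpression
#'   call when a per-sample tumor table is supplied (default 0.05).
#' @param ranking_key How final candidates are ordered: by codon-bias
#'   `"fold_enrichment"` (default) or by `"log2fc_te_oe"`; descending, ties
#'   broken lexicographically by gene_id.
#' @return A `funnel_config` list.
#' @export
funnel_config <- function(bias_threshold = 1.5,
                          codon_subset = c("TCC", "CTC", "CGC"),
                          oe_alpha = 0.05,
                          ranking_key = c("fold_enrichment", "log2fc_te_oe")) {
  ranking_key <- match.arg(ranking_key)
  if (!is.numeric(bias_threshold) || bias_threshold < 0) {
    adat_abort("invalid_configuration", "bias_threshold must be >= 0")
  }
  dep <- adat_codon_model()$dependent_codons
  extra <- setdiff(codon_subset, dep)
  if (length(extra) > 0) {
    adat_abort("invalid_configuration", paste0(
      "codon_subset contains non-A-to-I-dependent codons: ",
      paste(extra, collapse = ", ")))
  }
  structure(list(bias_threshold = bias_threshold,
                 codon_subset = codon_subset,
                 oe_alpha = oe_alpha,
                 ranking_key = ranking_key),
            class = "funnel_config")
}

#' Call tumor-vs-normal overexpression per gene
#'
#' Accepts any of three evidence shapes and returns one call per gene:
#' a precomputed logical `overexpressed` column is used as-is; per-sample
#' expression columns named `tumor_*` / `normal_*` are compared by Wilcoxon
#' rank-sum test with Benjamini-Hochberg correction (overexpressed when
#' log2FC > 0 and q <= `alpha`); `mean_tumor` / `mean_normal` columns fall
#' back to the direction-only rule log2FC > 0.
#'
#' @param tumor Data frame with `gene_id` plus one of the evidence shapes.
#' @param alpha BH q-value cutoff for the rank-sum route (default 0.05).
#' @return A tibble with `gene_id`, `log2fc_tumor`, `q_value` (NA when no
#'   test was run) and logical `overexpressed`.
#' @export
call_overexpression <- function(tumor, alpha = 0.05) {
  if (!is.data.frame(tumor) || !("gene_id" %in% names(tumor))) {
    adat_abort("invalid_tumor_table", "tumor table must have a gene_id column")
  }
  tumor <- as_tibble(tumor)
  if ("overexpressed" %in% names(tumor)) {
    return(tibble(gene_id = tumor$gene_id,
                  log2fc_tumor = tumor[["log2fc_tumor"]] %||% NA_real_,
                  q_value = NA_real_,
                  overexpressed = as.logical(tumor$overexpressed)))
  }
  t_cols <- grep("^tumor_", names(tumor), value = TRUE)
  n_cols <- grep("^normal_", names(tumor), value = TRUE)
  if (length(t_cols) >= 2 && length(n_cols) >= 2) {
    tm <- as.matrix(tumor[, t_cols])
    nm <- as.matrix(tumor[, n_cols])
    lfc <- log2((rowMeans(tm) + 0.5) / (rowMeans(nm) + 0.5))
    p <- vapply(seq_len(nrow(tumor)), function(i) {
      wilcox.test(tm[i, ], nm[i, ], exact = FALSE)$p.value
    }, numeric(1))
    q <- p.adjust(p, method = "BH")
    return(tibble(gene_id = tumor$gene_id, log2fc_tumor = lfc,
                  q_value = q, overexpressed = lfc > 0 & q <= alpha))
  }
  if (all(c("mean_tumor", "mean_normal") %in% names(tumor))) {
    lfc <- log2((tumor$mean_tumor + 0.5) / (tumor$mean_normal + 0.5))
    return(tibble(gene_id = tumor$gene_id, log2fc_tumor = lfc,
                  q_value = NA_real_, overexpressed = lfc > 0))
  }
  adat_abort("invalid_tumor_table", paste0(
    "tumor table needs an `overexpressed` column, tumor_*/normal_* sample ",
    "columns (>= 2 each), or mean_tumor/mean_normal columns"))
}

#' Run the three-stage candidate funnel
#'
#' Executes the integrated screen: stage 1 keeps genes whose TE and Ribo-seq
#' abundance are concordantly promoted by ADAT2 overexpression and reduced
#' by knockout; stage 2 keeps those with A-to-I-dependent codon usage above
#' `bias_threshold`-fold the background; stage 3 keeps those overexpressed
#' in tumor vs. normal tissue (skipped, with a flag, when no tumor table is
#' supplied). Candidates are ranked deterministically.
#'
#' @param te Translation table from [translation_efficiency()] (needs
#'   `gene_id`, `concordant`, `log2fc_te_oe`).
#' @param bias Bias table from [codon_bias()] (needs `gene_id`,
#'   `fold_enrichment`).
#' @param tumor Optional tumor/normal evidence (see [call_overexpression()]).
#' @param config A [funnel_config()].
#'
#' @return An object of class `adat_funnel`: list with `stage1`, `stage2`,
#'   `stage3` (gene_id vectors, each a subset of the previous),
#'   `ranked_candidates`, `evidence` (one row per gene in the shared
#'   universe, with `stage_reached`), `dropped` (genes excluded with a
#'   reason), `tumor_filter_applied` and `config`. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
run_funnel <- function(te, bias, tumor = NULL, config = funnel_config()) {
  stopifnot(inherits(config, "funnel_config"))
  if (!all(c("gene_id", "concordant") %in% names(te))) {
    adat_abort("invalid_te_table", "te table needs gene_id and concordant columns")
  }
  if (!all(c("gene_id", "fold_enrichment") %in% names(bias))) {
    adat_abort("invalid_bias_table",
               "bias table needs gene_id and fold_enrichment columns")
  }
  te <- as_tibble(te)
  bias <- as_tibble(bias)
  universe <- te$gene_id
  if (length(intersect(universe, bias$gene_id)) == 0) {
    adat_abort("no_overlap", "te and bias tables share no gene_id")
  }

  dropped <- tibble(gene_id = character(), reason = character())
  stage1 <- te$gene_id[te$concordant]
  no_bias <- setdiff(stage1, bias$gene_id)
  if (length(no_bias) > 0) {
    warn(paste0("excluding ", length(no_bias),
                " concordant gene(s) without a bias score: ",
                paste(head(no_bias, 5), collapse = ", ")),
         class = "adatscan_incomplete_evidence")
    dropped <- dplyr::bind_rows(dropped, tibble(
      gene_id = no_bias, reason = "missing bias score"))
    stage1 <- setdiff(stage1, no_bias)
  }

  fold <- setNames(bias$fold_enrichment, bias$gene_id)
  stage2 <- stage1[fold[stage1] > config$bias_threshold]

  oe <- NULL
  if (!is.null(tumor)) {
    oe <- call_overexpression(tumor, alpha = config$oe_alpha)
    no_oe <- setdiff(stage2, oe$gene_id)
    if (length(no_oe) > 0) {
      warn(paste0("excluding ", length(no_oe),
                  " gene(s) without tumor evidence"),
           class = "adatscan_incomplete_evidence")
      dropped <- dplyr::bind_rows(dropped, tibble(
        gene_id = no_oe, reason = "missing tumor evidence"))
      stage2_eval <- setdiff(stage2, no_oe)
    } else {
      stage2_eval <- stage2
    }
    oe_flag <- setNames(oe$overexpressed, oe$gene_id)
    stage3 <- stage2_eval[oe_flag[stage2_eval]]
  } else {
    stage3 <- stage2
  }

  evidence <- te |>
    dplyr::left_join(bias, by = "gene_id") |>
    dplyr::mutate(stage_reached = (.data$gene_id %in% stage1) +
                    (.data$gene_id %in% stage2) +
                    (.data$gene_id %in% stage3))
  if (!is.null(oe)) {
    evidence <- dplyr::left_join(evidence, oe, by = "gene_id")
  }

  key <- evidence[[config$ranking_key]][match(stage3, evidence$gene_id)]
  ord <- order(-key, stage3)
  ranked <- stage3[ord]

  structure(list(
    stage1 = sort(stage1), stage2 = sort(stage2), stage3 = sort(stage3),
    ranked_candidates = ranked,
    evidence = evidence,
    dropped = dropped,
    tumor_filter_applied = !is.null(tumor),
    config = config
  ), class = "adat_funnel")
}

#' @export
print.adat_funnel <- function(x, ...) {
  cat("ADAT2 candidate funnel\n")
  cat("  stage 1 (TE/Ribo concordance):  ", length(x$stage1), "genes\n")
  cat("  stage 2 (codon bias > ", x$config$bias_threshold, "): ",
      length(x$stage2), " genes\n", sep = "")
  if (x$tumor_filter_applied) {
    cat("  stage 3 (tumor overexpression): ", length(x$stage3), "genes\n")
  } else {
    cat("  stage 3: overexpression filter skipped (no tumor table)\n")
  }
  if (length(x$ranked_candidates) > 0) {
    cat("  top candidates:",
        paste(head(x$ranked_candidates, 7), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Human-readable and machine-readable funnel report
#'
#' @param result An `adat_funnel` from [run_funnel()].
#' @return A list with `text` (character vector of report lines) and
#'   `table` (one row per gene in the input universe, with `stage_reached`
#'   and all evidence columns), suitable for writing with
#'   [readr::write_tsv()].
#' @export
funnel_report <- function(result) {
  stopifnot(inherits(result, "adat_funnel"))
  ev <- dplyr::arrange(result$evidence,
                       dplyr::desc(.data$stage_reached), .data$gene_id)
  lines <- c(
    "ADAT2 candidate funnel report",
    sprintf("stage1_concordant\t%d", length(result$stage1)),
    sprintf("stage2_codon_bias\t%d", length(result$stage2)),
    sprintf("stage3_overexpressed\t%d", length(result$stage3)),
    sprintf("tumor_filter_applied\t%s",
            ifelse(result$tumor_filter_applied, "yes",
                   "no (overexpression filter skipped; stage3 = stage2)")),
    sprintf("bias_threshold\t%g", result$config$bias_threshold),
    sprintf("codon_subset\t%s", paste(result$config$codon_subset,
                                      collapse = ",")),
    "",
    "ranked candidates:",
    if (length(result$ranked_candidates) > 0) {
      sprintf("  %d. %s", seq_along(result$ranked_candidates),
              result$ranked_candidates)
    } else "  (none)",
    if (nrow(result$dropped) > 0) {
      c("", "dropped genes:",
        sprintf("  %s\t%s", result$dropped$gene_id, result$dropped$reason))
    }
  )
  list(text = lines, table = ev)
}
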