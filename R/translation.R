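# Translation-efficiency metrics from matched RNA-seq / Ribo-seq count
# matrices under the four-condition design control_oe / adat2_oe /
# control_ko / adat2_ko.

check_counts <- function(counts, arg = "counts") {
  if (!is.data.frame(counts) || names(counts)[1] != "gene_id" ||
      ncol(counts) < 2) {
    adat_abort("invalid_counts", paste0(
      "`", arg, "` must have gene_id as first column plus sample columns"))
  }
  if (anyDuplicated(counts$gene_id)) {
    dup <- unique(counts$gene_id[duplicated(counts$gene_id)])
    adat_abort("duplicate_gene", paste0(
      "duplicate gene_id in `", arg, "`: ", paste(dup, collapse = ", ")))
  }
  m <- as.matrix(counts[, -1])
  if (any(!is.finite(m)) || any(m < 0)) {
    adat_abort("invalid_counts", paste0(
      "`", arg, "` contains negative or non-finite values"))
  }
  as_tibble(counts)
}

check_design <- function(design) {
  req <- c("sample_id", "assay", "condition", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    adat_abort("invalid_design", paste0(
      "design must have columns: ", paste(req, collapse = ", ")))
  }
  bad_assay <- setdiff(unique(design$assay), c("rna", "ribo"))
  if (length(bad_assay) > 0) {
    adat_abort("invalid_design", paste0(
      "unknown assay label: ", paste(bad_assay, collapse = ", "),
      " (allowed: rna, ribo)"))
  }
  bad_cond <- setdiff(unique(design$condition), .CONDITIONS)
  if (length(bad_cond) > 0) {
    adat_abort("invalid_design", paste0(
      "unknown condition label: ", paste(bad_cond, collapse = ", "),
      " (allowed: ", paste(.CONDITIONS, collapse = ", "), ")"))
  }
  as_tibble(design)
}

#' Counts-per-million normalization
#'
#' Scales each sample column to counts per million mapped reads. No
#' pseudocount is added here; downstream ratio computations add their own.
#'
#' @param counts Count table: `gene_id` first column, one column per sample.
#' @return A tibble of the same shape with each sample column summing to 1e6.
#' @examples
#' cpm_normalize(tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 3)))
#' @export
cpm_normalize <- function(counts) {
  counts <- check_counts(counts)
  m <- as.matrix(counts[, -1])
  lib <- colSums(m)
  if (any(lib == 0)) {
    adat_abort("degenerate_sample", paste0(
      "zero library size for sample: ",
      paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  out <- counts
  out[, -1] <- sweep(m, 2, lib, "/") * 1e6
  out
}

# mean CPM per condition for one assay; returns gene x condition tibble
condition_means <- function(counts, design, assay) {
  des <- design[design$assay == assay, ]
  samples <- intersect(names(counts)[-1], des$sample_id)
  if (length(samples) == 0) {
    adat_abort("unmatched_design", paste0(
      "no ", assay, " sample in the design matches the count columns"))
  }
  cpm <- cpm_normalize(counts[, c("gene_id", samples)])
  m <- as.matrix(cpm[, -1])
  cond <- des$condition[match(samples, des$sample_id)]
  out <- sapply(.CONDITIONS, function(cc) {
    cols <- which(cond == cc)
    if (length(cols) == 0) {
      adat_abort("unmatched_design", paste0(
        "condition ", cc, " has no ", assay, " samples"))
    }
    rowMeans(m[, cols, drop = FALSE])
  })
  dplyr::bind_cols(tibble(gene_id = cpm$gene_id), as_tibble(out))
}

#' Translation efficiency and the overexpression/knockout concordance call
#'
#' Computes, per gene, translation efficiency (TE = Ribo-seq/RNA-seq
#' abundance ratio) in each condition from CPM-normalized counts, the log2
#' fold changes of TE and of Ribo-seq abundance for ADAT2 overexpression
#' (vs. its control) and knockout (vs. its control), and the concordance
#' call used as the screen's first filter: TE and Ribo-seq both up under
#' overexpression and both down under knockout.
#'
#' TE per condition is `(mean ribo CPM + pc) / (mean rna CPM + pc)` with the
#' mean taken over replicates; the pseudocount keeps TE finite for
#' zero-count genes.
#'
#' @param rna,ribo Count tables (`gene_id` + sample columns) for the RNA-seq
#'   and Ribo-seq assays. Genes are intersected; both assays must contain
#'   samples for all four conditions.
#' @param design Design table with `sample_id`, `assay` (`rna`/`ribo`),
#'   `condition` (one of `control_oe`, `adat2_oe`, `control_ko`,
#'   `adat2_ko`) and `replicate`.
#' @param pseudocount CPM pseudocount (default 0.5).
#' @param min_abs_log2fc Optional magnitude cutoff applied to all four fold
#'   changes in the concordance call (default 0: direction only, matching
#'   the screen's stated rule).
#'
#' @return A tibble with one row per gene: TE per condition
#'   (`te_control_oe`, `te_adat2_oe`, `te_control_ko`, `te_adat2_ko`),
#'   `log2fc_te_oe`, `log2fc_te_ko`, `log2fc_ribo_oe`, `log2fc_ribo_ko`,
#'   and logical `concordant`.
#' @export
translation_efficiency <- function(rna, ribo, design, pseudocount = 0.5,
                                   min_abs_log2fc = 0) {
  stopifnot(pseudocount > 0, min_abs_log2fc >= 0)
  rna <- check_counts(rna, "rna")
  ribo <- check_counts(ribo, "ribo")
  design <- check_design(design)

  genes <- intersect(rna$gene_id, ribo$gene_id)
  if (length(genes) == 0) {
    adat_abort("no_overlap", "rna and ribo share no gene_id")
  }
  rna <- rna[match(genes, rna$gene_id), ]
  ribo <- ribo[match(genes, ribo$gene_id), ]

  rna_m <- condition_means(rna, design, "rna")
  ribo_m <- condition_means(ribo, design, "ribo")

  te <- lapply(.CONDITIONS, function(cc) {
    (ribo_m[[cc]] + pseudocount) / (rna_m[[cc]] + pseudocount)
  })
  names(te) <- paste0("te_", .CONDITIONS)

  out <- dplyr::bind_cols(tibble(gene_id = genes), as_tibble(te))
  out$log2fc_te_oe <- log2(out$te_adat2_oe / out$te_control_oe)
  out$log2fc_te_ko <- log2(out$te_adat2_ko / out$te_control_ko)
  out$log2fc_ribo_oe <- log2((ribo_m$adat2_oe + pseudocount) /
                             (ribo_m$control_oe + pseudocount))
  out$log2fc_ribo_ko <- log2((ribo_m$adat2_ko + pseudocount) /
                             (ribo_m$control_ko + pseudocount))
  out$concordant <- out$log2fc_te_oe > min_abs_log2fc &
    out$log2fc_ribo_oe > min_abs_log2fc &
    out$log2fc_te_ko < -min_abs_log2fc &
    out$log2fc_ribo_ko < -min_abs_log2fc
  out
}

#' Classify polysome-profiling fractions by translational state
#'
#' Maps sucrose-gradient fraction labels to the three translational states
#' used when profiling an mRNA's ribosome loading: material lighter than the
#' small subunit is untranslated, the 40S/60S/80S fractions reflect
#' translation initiation, and polysomes (heavier than 80S) reflect active
#' translation.
#'
#' @param fraction_label Character vector of labels; each must be one of
#'   `sub40S`, `40S`, `60S`, `80S`, `polysome`.
#' @return A character vector over `untranslated`, `initiation`, `active`.
#' @examples
#' classify_polysome_fraction(c("sub40S", "80S", "polysome"))
#' @export
classify_polysome_fraction <- function(fraction_label) {
  map <- c(sub40S = "untranslated", `40S` = "initiation",
           `60S` = "initiation", `80S` = "initiation",
           polysome = "active")
  bad <- setdiff(unique(fraction_label), names(map))
  if (length(bad) > 0) {
    adat_abort("invalid_label", paste0(
      "unknown fraction label: ", paste(bad, collapse = ", "),
      " (allowed: ", paste(names(map), collapse = ", "), ")"))
  }
  unname(map[fraction_label])
}
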