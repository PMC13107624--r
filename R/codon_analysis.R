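#' Per-gene codon usage counts
#'
#' Counts every codon of each in-frame coding sequence. Stop codons are
#' counted here but excluded from usage fractions downstream (they are not
#' decoded by tRNAs).
#'
#' @param cds A data frame with columns `gene_id` and `sequence` (in-frame
#'   CDS over A/C/G/T; U is mapped to T), or a named character vector.
#'
#' @return A tibble with columns `gene_id`, `codon`, `count`, with all 64
#'   codons present for every gene (zero counts included). Counts for a gene
#'   sum to its length in codons.
#'
#' @examples
#' u <- codon_usage(c(g1 = "ATGTCCTCC"))
#' u[u$count > 0, ]
#' @export
codon_usage <- function(cds) {
  cds <- check_cds(cds)
  codons <- all_codons()
  n_cod <- nchar(cds$sequence) %/% 3L
  gene <- rep(cds$gene_id, n_cod)
  cod <- unlist(lapply(cds$sequence, split_codons), use.names = FALSE)
  tab <- table(factor(gene, levels = cds$gene_id),
               factor(cod, levels = codons))
  tibble(
    gene_id = rep(cds$gene_id, each = length(codons)),
    codon   = rep(codons, times = nrow(cds)),
    count   = as.integer(t(tab))
  )
}

# aggregate a usage table (or a CDS table) into background codon totals
codon_totals <- function(x) {
  if (is.data.frame(x) && all(c("codon", "count") %in% names(x)) &&
      !("sequence" %in% names(x))) {
    out <- dplyr::summarise(dplyr::group_by(x, .data$codon),
                            count = sum(.data$count), .groups = "drop")
  } else {
    out <- codon_totals(codon_usage(x))
  }
  out
}

# fraction of (non-stop) codons that belong to `subset`
dep_fraction <- function(totals, subset) {
  keep <- !(totals$codon %in% .STOP_CODONS)
  denom <- sum(totals$count[keep])
  if (denom == 0) return(NA_real_)
  sum(totals$count[totals$codon %in% subset & keep]) / denom
}

#' Codon-usage-bias score for A-to-I-dependent codons
#'
#' Scores each gene's usage of the inosine-dependent codons against a
#' background computed over all supplied coding sequences, mirroring the
#' candidate screen's "usage > 1.5-fold higher than all protein-coding
#' genes" filter. Usage is the fraction of a gene's non-stop codons drawn
#' from the scored codon set; fold enrichment is the gene fraction divided
#' by the background fraction.
#'
#' @param cds CDS table (see [codon_usage()]) for the genes to score.
#' @param model An [adat_codon_model()]; its `codon_subset` defines which
#'   dependent codons are scored unless `codon_subset` is given here.
#' @param background Optional background: another CDS table or a
#'   codon/count table. Defaults to `cds` itself (background over all
#'   supplied protein-coding sequences).
#' @param codon_subset Optional codon subset overriding the model's.
#' @param threshold Fold-enrichment cutoff recorded in the `pass` column
#'   (default 1.5).
#'
#' @return A tibble with `gene_id`, `dep_usage_gene`, `dep_usage_background`,
#'   `fold_enrichment` and logical `pass` (`fold_enrichment > threshold`).
#'
#' @examples
#' cds <- simulate_cds(n_genes = 20, length_codons = 100, seed = 1)
#' codon_bias(cds, codon_subset = c("TCC", "CTC", "CGC"))
#' @export
codon_bias <- function(cds, model = adat_codon_model(), background = NULL,
                       codon_subset = NULL, threshold = 1.5) {
  subset <- codon_subset %||% model$codon_subset
  extra <- setdiff(subset, model$dependent_codons)
  if (length(extra) > 0) {
    adat_abort("invalid_configuration", paste0(
      "codon_subset contains non-A-to-I-dependent codons: ",
      paste(extra, collapse = ", ")))
  }
  usage <- codon_usage(cds)
  bg_totals <- codon_totals(background %||% usage)
  bg_frac <- dep_fraction(bg_totals, subset)
  if (is.na(bg_frac) || bg_frac == 0) {
    adat_abort("undefined_fold", paste0(
      "background usage of the scored codons (",
      paste(subset, collapse = ", "),
      ") is zero: fold enrichment is undefined"))
  }
  out <- usage |>
    dplyr::filter(!(.data$codon %in% .STOP_CODONS)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      dep_usage_gene = sum(.data$count[.data$codon %in% subset]) /
        sum(.data$count),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dep_usage_background = bg_frac,
      fold_enrichment = .data$dep_usage_gene / bg_frac,
      pass = .data$fold_enrichment > threshold
    )
  # preserve input gene order
  out <- out[match(unique(usage$gene_id), out$gene_id), ]
  attr(out, "threshold") <- threshold
  attr(out, "codon_subset") <- subset
  out
}

#' Synonymously recode away all A-to-I-dependent codons
#'
#' Replaces every strictly inosine-dependent codon with a synonymous codon
#' whose decoding does not require A-to-I tRNA modification, as used to
#' construct an A-to-I-independent reporter. The protein sequence is
#' unchanged; the output contains no dependent codons; applying the recoder
#' twice is a no-op.
#'
#' @param cds CDS table (see [codon_usage()]).
#' @param model An [adat_codon_model()] supplying the recode map. All eight
#'   dependent codons are always recoded regardless of the model's scoring
#'   subset.
#'
#' @return A list with
#'   \describe{
#'     \item{cds}{tibble of recoded sequences (`gene_id`, `sequence`).}
#'     \item{report}{tibble of edits: `gene_id`, `codon_index` (0-based),
#'       `old_codon`, `new_codon`.}
#'   }
#'
#' @examples
#' recode_cds(c(g1 = "ATGTCC"))
#' @export
recode_cds <- function(cds, model = adat_codon_model()) {
  cds <- check_cds(cds)
  map <- model$recode_map
  res <- purrr::map2(cds$gene_id, cds$sequence, function(g, s) {
    cod <- split_codons(s)
    hit <- which(cod %in% names(map))
    old <- cod[hit]
    cod[hit] <- map[old]
    list(
      sequence = paste(cod, collapse = ""),
      report = tibble(gene_id = rep(g, length(hit)),
                      codon_index = hit - 1L,
                      old_codon = old,
                      new_codon = unname(map[old]))
    )
  })
  list(
    cds = tibble(gene_id = cds$gene_id,
                 sequence = vapply(res, `[[`, character(1), "sequence")),
    report = dplyr::bind_rows(lapply(res, `[[`, "report"))
  )
}

#' Translate coding sequences under the standard genetic code
#'
#' @param cds CDS table (see [codon_usage()]).
#' @return A tibble with `gene_id` and `protein` (stop as `*`).
#' @examples
#' translate_cds(c(g1 = "ATGTCCTAA"))
#' @export
translate_cds <- function(cds) {
  cds <- check_cds(cds)
  gc <- Biostrings::GENETIC_CODE
  tibble(
    gene_id = cds$gene_id,
    protein = vapply(cds$sequence, function(s) {
      paste(gc[split_codons(s)], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  )
}
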