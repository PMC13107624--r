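# Fixtures built in code. rand_cds is deliberately independent of
# simulate_cds: it draws sense codons uniformly, so it exercises the codon
# machinery without sharing the generator's code path.

ALL_CODONS <- local({
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
})
SENSE_CODONS <- setdiff(ALL_CODONS, c("TAA", "TAG", "TGA"))

rand_cds <- function(n, len_codons = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    gene_id = sprintf("r%04d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(SENSE_CODONS, len_codons, replace = TRUE), collapse = "")
    }, character(1))
  )
}

# hand-built 10-gene funnel toy: predicate outcomes fixed by construction.
# 4 concordant; of those, 2 pass bias at 1.5; of those, 1 overexpressed.
toy_funnel_inputs <- function() {
  genes <- sprintf("t%02d", 1:10)
  concordant <- genes %in% c("t01", "t02", "t03", "t04")
  lfc <- ifelse(concordant, 1, -1)
  te <- tibble::tibble(
    gene_id = genes,
    log2fc_te_oe = lfc, log2fc_ribo_oe = lfc,
    log2fc_te_ko = -lfc, log2fc_ribo_ko = -lfc,
    concordant = concordant
  )
  fold <- c(t01 = 2.0, t02 = 1.8, t03 = 1.2, t04 = 0.9, t05 = 3.0,
            t06 = 1.6, t07 = 0.5, t08 = 1.0, t09 = 2.5, t10 = 0.2)
  bias <- tibble::tibble(gene_id = genes,
                         dep_usage_gene = unname(fold) * 0.05,
                         dep_usage_background = 0.05,
                         fold_enrichment = unname(fold))
  tumor <- tibble::tibble(gene_id = genes,
                          overexpressed = genes %in% c("t01", "t05", "t09"))
  list(te = te, bias = bias, tumor = tumor, genes = genes)
}

# brute-force reapplication of the three funnel predicates
toy_funnel_oracle <- function(inp, threshold = 1.5) {
  s1 <- character()
  for (g in inp$genes) {
    if (inp$te$concordant[inp$te$gene_id == g]) s1 <- c(s1, g)
  }
  s2 <- character()
  for (g in s1) {
    if (inp$bias$fold_enrichment[inp$bias$gene_id == g] > threshold) {
      s2 <- c(s2, g)
    }
  }
  s3 <- character()
  for (g in s2) {
    if (inp$tumor$overexpressed[inp$tumor$gene_id == g]) s3 <- c(s3, g)
  }
  list(stage1 = sort(s1), stage2 = sort(s2), stage3 = sort(s3))
}

# small pileup row constructor
pileup_row <- function(family_id = "Ser-AGA", pos = 34, ref = "A",
                       A = 0, C = 0, G = 0, T = 0) {
  tibble::tibble(family_id = family_id, sprinzl_pos = pos, ref_base = ref,
                 count_A = A, count_C = C, count_G = G, count_T = T)
}
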