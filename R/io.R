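# Readers and writers for the pipeline's plain-text contracts: FASTA for
# CDS, TSV for counts / design / pileups / results. Readers validate
# against the documented schemas and name the offending record on failure;
# writers are deterministic (fixed column order, tab separator, '.'
# decimal, LF endings).

#' Read coding sequences from a FASTA file
#'
#' The first whitespace-delimited token of each description line is the
#' gene id; U is mapped to T. Records violating the CDS invariants (length
#' a positive multiple of 3, alphabet A/C/G/T) are rejected individually
#' with a reason — they do not abort the whole file — and reported via a
#' warning and the `rejected` attribute of the result.
#'
#' @param path FASTA file.
#' @return A tibble with `gene_id` and `sequence`; attribute `rejected` is
#'   a tibble (`record`, `gene_id`, `reason`) of skipped records.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) {
    adat_abort("io", paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    adat_abort("io", paste0("cannot parse FASTA: ",
                                            conditionMessage(e)))
                  })
  if (length(set) == 0) {
    adat_abort("io", paste0("FASTA file contains no records: ", path))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- chartr("U", "T", toupper(as.character(set)))
  n <- nchar(seqs)
  reason <- dplyr::case_when(
    grepl("[^ACGT]", seqs) ~ "alphabet outside {A,C,G,T,U}",
    n < 3 ~ "shorter than one codon",
    n %% 3 != 0 ~ "length not divisible by 3",
    TRUE ~ NA_character_
  )
  bad <- !is.na(reason)
  rejected <- tibble(record = which(bad), gene_id = ids[bad],
                     reason = reason[bad])
  if (any(bad)) {
    warn(paste0("rejected ", sum(bad), " FASTA record(s): ",
                paste(paste0(ids[bad], " (", reason[bad], ")"),
                      collapse = "; ")),
         class = "adatscan_rejected_records")
  }
  out <- check_cds(tibble(gene_id = ids[!bad], sequence = unname(seqs[!bad])))
  attr(out, "rejected") <- rejected
  out
}

#' Write coding sequences to FASTA
#'
#' @param cds CDS table (`gene_id`, `sequence`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_cds_fasta <- function(cds, path) {
  cds <- check_cds(cds)
  set <- Biostrings::DNAStringSet(setNames(cds$sequence, cds$gene_id))
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

#' Read a gene-by-sample count table
#'
#' First column `gene_id`, remaining columns one per sample. Duplicate gene
#' ids and negative counts are errors naming the offender.
#'
#' @param path TSV file.
#' @return A count tibble.
#' @export
read_counts_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2 || names(x)[1] != "gene_id") {
    adat_abort("schema", paste0(
      "counts file must start with a gene_id column: ", path))
  }
  check_counts(x, basename(path))
}

#' Read a sample design table
#'
#' Required columns: `sample_id`, `assay` (`rna`/`ribo`), `condition`
#' (`control_oe`, `adat2_oe`, `control_ko`, `adat2_ko`), `replicate`.
#'
#' @param path TSV file.
#' @return A design tibble.
#' @export
read_design_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "assay", "condition", "replicate")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    adat_abort("schema", paste0(
      "design file missing column(s): ", paste(miss, collapse = ", ")))
  }
  check_design(x)
}

#' Read a tRNA positional pileup table
#'
#' Columns: `family_id`, `sprinzl_pos` (1-based Sprinzl numbering, taken as
#' given), `ref_base`, `count_A`, `count_C`, `count_G`, `count_T`.
#'
#' @param path TSV file.
#' @return A pileup tibble.
#' @export
read_pileup_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_pileup(x, basename(path))
}

#' Read a tumor/normal expression table
#'
#' Accepts any of the shapes understood by [call_overexpression()].
#'
#' @param path TSV file.
#' @return A tibble with `gene_id` plus evidence columns.
#' @export
read_tumor_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!("gene_id" %in% names(x))) {
    adat_abort("schema", paste0("tumor table needs a gene_id column: ", path))
  }
  as_tibble(x)
}
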