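# shared validation helpers; every abort carries a package-prefixed class so
# callers (and the CLI) can dispatch on failure kind.

adat_abort <- function(code, msg) {
  abort(msg, class = c(paste0("adatscan_", code), "adatscan_error"))
}

`%||%` <- rlang::`%||%`

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.CONDITIONS <- c("control_oe", "adat2_oe", "control_ko", "adat2_ko")

.STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# split an in-frame sequence into its codons
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# coerce/validate a CDS table: tibble with gene_id + sequence over {A,C,G,T},
# U mapped to T, length a positive multiple of 3. Aborts on violation since
# downstream operations assume a valid CodingSequence.
check_cds <- function(cds, arg = "cds") {
  if (is.character(cds)) {
    ids <- names(cds) %||% paste0("seq", seq_along(cds))
    cds <- tibble(gene_id = ids, sequence = unname(cds))
  }
  if (!is.data.frame(cds) || !all(c("gene_id", "sequence") %in% names(cds))) {
    adat_abort("invalid_cds",
               paste0("`", arg, "` must be a data frame with columns gene_id and sequence"))
  }
  cds <- as_tibble(cds)
  seqs <- chartr("u", "U", toupper(cds$sequence))
  seqs <- chartr("U", "T", seqs)
  bad_alpha <- grepl("[^ACGT]", seqs)
  if (any(bad_alpha)) {
    adat_abort("invalid_cds", paste0(
      "sequence alphabet outside {A,C,G,T,U} for: ",
      paste(cds$gene_id[bad_alpha], collapse = ", ")))
  }
  n <- nchar(seqs)
  bad_len <- n < 3L | n %% 3L != 0L
  if (any(bad_len)) {
    adat_abort("invalid_cds", paste0(
      "sequence length not a positive multiple of 3 for: ",
      paste(cds$gene_id[bad_len], collapse = ", ")))
  }
  if (anyDuplicated(cds$gene_id)) {
    dup <- unique(cds$gene_id[duplicated(cds$gene_id)])
    adat_abort("duplicate_gene", paste0(
      "duplicate gene_id: ", paste(dup, collapse = ", ")))
  }
  cds$sequence <- seqs
  cds[, c("gene_id", "sequence")]
}

# deterministic TSV writer: fixed column order as given, tab separated,
# '.' decimal mark, LF line endings (readr guarantees all three).
write_tsv_det <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", eol = "\n", progress = FALSE)
  invisible(path)
}
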