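# The ADAT2/ADAT3 heterodimer deaminates A34 -> I34 in exactly eight human
# tRNA families. Inosine at the wobble position pairs with C, U and A at the
# third codon base, but only the C-ending codon of each box has *no* other
# cognate tRNA: it is decoded exclusively through the I34:C wobble pair and
# is therefore "strictly A-to-I dependent".

# one-letter -> three-letter amino-acid codes (sense codons only)
.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val")

# anticodons written 5'->3' with the wobble base (position 34) first,
# in the order the eight families are conventionally listed
.ADAT_ANTICODONS <- c(Leu = "AAG", Arg = "ACG", Ser = "AGA", Pro = "AGG",
                      Ala = "AGC", Val = "AAC", Ile = "AAT", Thr = "AGT")

# codon read through the I34:C3 pair: codon base 1 pairs anticodon base 36,
# base 2 pairs base 35, and the wobble-dependent third base is C
wobble_dependent_codon <- function(anticodon) {
  vapply(anticodon, function(ac) {
    paste0(.COMPLEMENT[[substr(ac, 3, 3)]],
           .COMPLEMENT[[substr(ac, 2, 2)]], "C")
  }, character(1), USE.NAMES = FALSE)
}

# synonymous replacement that needs no inosine: NNC -> NNG (G-ending codons
# are read by C34 isoacceptors, never by I34). Ile has no G-ending codon and
# ATT is itself I34-decoded, so ATC -> ATA (decoded by a distinct tRNA).
default_recode_map <- function(dependent_codons) {
  repl <- ifelse(dependent_codons == "ATC", "ATA",
                 paste0(substr(dependent_codons, 1, 2), "G"))
  setNames(repl, dependent_codons)
}

#' Wobble-pairing model of the eight ADAT-substrate tRNA families
#'
#' Builds the model of the eight human tRNA anticodon families carrying an
#' adenosine at the wobble position (Sprinzl 34) that ADAT2 deaminates to
#' inosine, the set of strictly A-to-I-dependent codons each family decodes
#' through the I34:C wobble pair, and a synonymous recoding map that removes
#' the inosine requirement.
#'
#' Each family's dependent codon is derived from its anticodon by reverse
#' pairing: codon bases 1 and 2 are the complements of anticodon bases 36 and
#' 35, and the third base is C — the only third base for which no other
#' cognate tRNA exists, so decoding is essentially abolished without inosine.
#' All eight dependent codons therefore end in C.
#'
#' @param codon_subset Optional character vector restricting downstream
#'   scoring to a subset of the dependent codons (the candidate screen uses
#'   `c("TCC", "CTC", "CGC")`, the codons of the three families whose
#'   modification responds most strongly to ADAT2 manipulation). Must be a
#'   subset of the eight dependent codons.
#'
#' @return An object of class `adat_codon_model`: a list with
#'   \describe{
#'     \item{families}{tibble with `family_id`, `amino_acid` (3-letter code),
#'       `anticodon` (5'->3', wobble base first) and `dependent_codon`.}
#'     \item{dependent_codons}{character vector of the 8 strictly
#'       inosine-dependent codons.}
#'     \item{recode_map}{named character vector mapping each dependent codon
#'       to its synonymous, inosine-independent replacement.}
#'     \item{codon_subset}{the active scoring subset (all 8 by default).}
#'   }
#'
#' @examples
#' m <- adat_codon_model()
#' m$families
#' m$recode_map
#' adat_codon_model(codon_subset = c("TCC", "CTC", "CGC"))$codon_subset
#' @export
adat_codon_model <- function(codon_subset = NULL) {
  families <- tibble(
    amino_acid = names(.ADAT_ANTICODONS),
    anticodon  = unname(.ADAT_ANTICODONS),
    dependent_codon = wobble_dependent_codon(unname(.ADAT_ANTICODONS))
  )
  families$family_id <- paste(families$amino_acid, families$anticodon, sep = "-")
  families <- families[, c("family_id", "amino_acid", "anticodon", "dependent_codon")]

  dep <- families$dependent_codon
  map <- default_recode_map(dep)

  # internal consistency: replacements are synonymous and inosine-independent
  gc <- Biostrings::GENETIC_CODE
  stopifnot(all(gc[names(map)] == gc[map]), !any(map %in% dep))

  if (!is.null(codon_subset)) {
    extra <- setdiff(codon_subset, dep)
    if (length(extra) > 0) {
      adat_abort("invalid_configuration", paste0(
        "codon_subset contains non-A-to-I-dependent codons: ",
        paste(extra, collapse = ", "),
        " (allowed: ", paste(dep, collapse = ", "), ")"))
    }
    subset <- unique(codon_subset)
  } else {
    subset <- dep
  }

  structure(
    list(families = families, dependent_codons = dep,
         recode_map = map, codon_subset = subset),
    class = "adat_codon_model"
  )
}

#' @export
print.adat_codon_model <- function(x, ...) {
  cat("ADAT wobble-inosine codon model:", nrow(x$families),
      "anticodon families\n")
  print(x$families)
  cat("scoring subset:", paste(x$codon_subset, collapse = ", "), "\n")
  invisible(x)
}
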