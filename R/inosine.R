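# Inosine is read as guanosine by reverse transcriptases, so the wobble
# inosine fraction of an ADAT-substrate tRNA family is estimated from the
# A->G mismatch fraction at Sprinzl position 34 in a tRNA-seq pileup.

check_pileup <- function(pileup, arg = "pileup") {
  req <- c("family_id", "sprinzl_pos", "ref_base",
           "count_A", "count_C", "count_G", "count_T")
  if (!is.data.frame(pileup) || !all(req %in% names(pileup))) {
    adat_abort("malformed_pileup", paste0(
      "`", arg, "` must have columns: ", paste(req, collapse = ", ")))
  }
  cnt <- as.matrix(pileup[, c("count_A", "count_C", "count_G", "count_T")])
  if (any(!is.finite(cnt)) || any(cnt < 0)) {
    adat_abort("malformed_pileup", "pileup counts must be non-negative integers")
  }
  as_tibble(pileup)
}

#' Estimate wobble-position inosine fractions from tRNA-seq pileups
#'
#' For each tRNA family in a positional base-count pileup, estimates the
#' inosine fraction at the wobble position (Sprinzl 34) as the G fraction
#' among A+G reads — the standard sequencing surrogate, since reverse
#' transcriptases read inosine as G. C and T counts at position 34 are
#' treated as sequencing error: they do not enter the fraction but do count
#' toward coverage.
#'
#' @param pileup Pileup table with columns `family_id`, `sprinzl_pos`,
#'   `ref_base`, `count_A`, `count_C`, `count_G`, `count_T` (see
#'   [read_pileup_tsv()]).
#' @param min_coverage Families with position-34 coverage below this are
#'   flagged (default 100) and excluded from fold-change computation
#'   downstream.
#'
#' @return A tibble, one row per family: `family_id`, `count_a`, `count_g`,
#'   `i_fraction` (= G/(A+G)), `i_to_a_ratio` (= G/A; `Inf` when A = 0),
#'   `coverage` (= A+C+G+T at position 34) and `flag_low_coverage`.
#'
#' @examples
#' p <- tibble::tibble(family_id = "Ser-AGA", sprinzl_pos = 34, ref_base = "A",
#'                     count_A = 50, count_C = 0, count_G = 50, count_T = 0)
#' estimate_inosine(p, min_coverage = 10)
#' @export
estimate_inosine <- function(pileup, min_coverage = 100) {
  pileup <- check_pileup(pileup)
  stopifnot(min_coverage >= 1)
  fams <- unique(pileup$family_id)
  at34 <- pileup[pileup$sprinzl_pos == 34L, ]
  missing34 <- setdiff(fams, at34$family_id)
  if (length(missing34) > 0) {
    adat_abort("malformed_pileup", paste0(
      "no Sprinzl position 34 record for family: ",
      paste(missing34, collapse = ", ")))
  }
  not_a <- at34$family_id[at34$ref_base != "A"]
  if (length(not_a) > 0) {
    adat_abort("family_mismatch", paste0(
      "reference base at position 34 is not A for family: ",
      paste(not_a, collapse = ", "),
      " (not an ADAT-substrate family?)"))
  }
  at34 <- at34[match(fams, at34$family_id), ]
  a <- at34$count_A
  g <- at34$count_G
  cov <- a + at34$count_C + g + at34$count_T
  tibble(
    family_id = fams,
    count_a = as.integer(a),
    count_g = as.integer(g),
    i_fraction = ifelse(a + g > 0, g / (a + g), NA_real_),
    i_to_a_ratio = ifelse(a > 0, g / a, ifelse(g > 0, Inf, NA_real_)),
    coverage = as.integer(cov),
    flag_low_coverage = cov < min_coverage
  )
}

#' Per-family fold change in inosine levels between conditions
#'
#' Compares I-to-A ratios between a case condition (e.g. ADAT2
#' overexpression or knockout) and its control, family by family. Families
#' flagged for low coverage in either input are excluded. The fold change is
#' pseudocount-stabilized: `(ratio_case + pc) / (ratio_control + pc)`, so
#' swapping case and control exactly negates the log2 fold change.
#'
#' @param case,control Estimate tables from [estimate_inosine()].
#' @param pseudocount Added to both ratios before dividing (default 0.01).
#'
#' @return A tibble with `family_id`, `ratio_case`, `ratio_control`,
#'   `fold_change` and `log2_fold_change`, ordered by decreasing fold.
#' @export
inosine_fold_change <- function(case, control, pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  keep <- function(x) x[!x$flag_low_coverage, c("family_id", "i_to_a_ratio")]
  joined <- dplyr::inner_join(
    dplyr::rename(keep(case), ratio_case = "i_to_a_ratio"),
    dplyr::rename(keep(control), ratio_control = "i_to_a_ratio"),
    by = "family_id"
  )
  if (nrow(joined) == 0) {
    adat_abort("no_common_family",
               "case and control share no family with adequate coverage")
  }
  joined |>
    dplyr::mutate(
      fold_change = (.data$ratio_case + pseudocount) /
        (.data$ratio_control + pseudocount),
      log2_fold_change = log2(.data$fold_change)
    ) |>
    dplyr::arrange(dplyr::desc(.data$fold_change), .data$family_id)
}
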