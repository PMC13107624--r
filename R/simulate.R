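# Ground-truthed generators for every pipeline stage. The translation model
# is a minimal multiplicative effect model linking wobble-inosine supply to
# ribosome loading of codon-biased genes -- a testing harness with known
# truth, not a mechanistic elongation simulator.

# non-ADAT amino acids (1-letter); their codons are never inosine-dependent
.NON_ADAT_AA <- c("F", "M", "Y", "H", "Q", "N", "K", "D", "E", "C", "W", "G")

# codon sampling distribution for one gene: ADAT-family amino acids take a
# fixed total share, uniform across the 8 families; within a family the
# codon is Bernoulli between the dependent codon and its inosine-independent
# synonym, so the gene's dependent-codon fraction has a controllable target.
codon_sampling_probs <- function(target_dep_fraction, adat_share = 0.4) {
  if (target_dep_fraction < 0 || target_dep_fraction > adat_share) {
    adat_abort("infeasible_fraction", paste0(
      "target dependent-codon fraction ", target_dep_fraction,
      " is not realizable: the ADAT-family amino-acid share is ", adat_share))
  }
  model <- adat_codon_model()
  p_dep <- target_dep_fraction / adat_share
  dep <- model$dependent_codons
  alt <- unname(model$recode_map[dep])

  gc <- Biostrings::GENETIC_CODE
  other <- unlist(lapply(.NON_ADAT_AA, function(aa) {
    syn <- names(gc)[gc == aa]
    setNames(rep((1 - adat_share) / length(.NON_ADAT_AA) / length(syn),
                 length(syn)), syn)
  }))
  c(setNames(rep(adat_share * p_dep / 8, 8), dep),
    setNames(rep(adat_share * (1 - p_dep) / 8, 8), alt),
    other)
}

#' Simulate coding sequences with controlled A-to-I-dependent codon usage
#'
#' Generates in-frame CDS (ATG start, no internal stops, TAA appended) whose
#' realized fraction of inosine-dependent codons is binomially distributed
#' around a per-gene target: background genes around
#' `dep_fraction_background`, planted genes around their own target.
#'
#' @param n_genes Number of genes.
#' @param length_codons Sense codons per gene, including the start codon
#'   (a TAA stop is appended on top); must be >= 10.
#' @param dep_fraction_background Target dependent-codon fraction for
#'   unplanted genes (default 0.12, a realistic proteome-wide total for the
#'   eight C-ending codons).
#' @param planted Named numeric vector, gene_id -> target dependent-codon
#'   fraction, overriding the background for those genes. Names must be in
#'   the generated universe (`g0001`...).
#' @param adat_share Total share of codons drawn from the eight ADAT-family
#'   amino acids (default 0.4); targets above this are infeasible.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so a bundle draws everything from one stream).
#'
#' @return A tibble with `gene_id` and `sequence`.
#' @examples
#' simulate_cds(n_genes = 2, length_codons = 12, seed = 1)
#' @export
simulate_cds <- function(n_genes, length_codons = 300,
                         dep_fraction_background = 0.12, planted = NULL,
                         adat_share = 0.4, seed = NULL) {
  stopifnot(n_genes >= 1, length_codons >= 10)
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  targets <- setNames(rep(dep_fraction_background, n_genes), gene_ids)
  if (!is.null(planted)) {
    unknown <- setdiff(names(planted), gene_ids)
    if (length(unknown) > 0) {
      adat_abort("invalid_configuration", paste0(
        "planted genes outside the generated universe: ",
        paste(unknown, collapse = ", ")))
    }
    targets[names(planted)] <- planted
  }
  # one sampling distribution per distinct target
  probs <- lapply(split(gene_ids, targets), function(g) {
    codon_sampling_probs(as.numeric(unique(targets[g[1]])), adat_share)
  })
  seqs <- vapply(gene_ids, function(g) {
    p <- probs[[as.character(targets[[g]])]]
    body <- sample(names(p), length_codons - 1L, replace = TRUE, prob = p)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }, character(1), USE.NAMES = FALSE)
  tibble(gene_id = gene_ids, sequence = seqs)
}

#' Per-condition wobble inosine fractions used by the default simulation
#'
#' Controls sit at an intermediate modification level (0.5); ADAT2
#' overexpression raises all eight families to 0.9 and knockout lowers them
#' to 0.1, so inosine supply tracks ADAT2 dose.
#'
#' @return A tibble with `family_id`, `condition`, `i_fraction`.
#' @export
default_i_fractions <- function() {
  fam <- adat_codon_model()$families$family_id
  tidyr::expand_grid(family_id = fam, condition = .CONDITIONS) |>
    dplyr::mutate(i_fraction = dplyr::case_when(
      .data$condition == "adat2_oe" ~ 0.9,
      .data$condition == "adat2_ko" ~ 0.1,
      TRUE ~ 0.5
    ))
}

#' Simulate matched RNA-seq and Ribo-seq count matrices
#'
#' RNA abundances are log-normal per gene and constant across conditions;
#' RNA counts are multinomial over genes at the given library size.
#' Ribosome loading multiplies each gene's abundance by
#' `2^(effect * mean_I34(condition) * dep_fraction_gene / dep_background)`,
#' where `effect` is the gene's planted log2 effect size (0 for
#' non-responders) and `mean_I34` averages the wobble inosine fractions of
#' the focal tRNA families in that condition. Since overexpression raises
#' and knockout lowers inosine supply, planted codon-biased responders are
#' TE-concordant by construction; all other genes are null.
#'
#' @param cds CDS table whose realized dependent-codon fractions drive the
#'   effect (see [simulate_cds()]).
#' @param truth Truth list as assembled by [simulate_bundle()]: needs
#'   `i_fractions`, `responders` (named log2 effects), `subset_families`,
#'   `dep_fraction_background`, `replicates`, `library_size`.
#' @param seed Optional seed (`NULL`: current stream).
#'
#' @return A list with count tibbles `rna` and `ribo` (gene_id + sample
#'   columns) and the `design` tibble.
#' @export
simulate_counts <- function(cds, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds <- check_cds(cds)
  model <- adat_codon_model()
  n <- nrow(cds)

  usage <- codon_usage(cds)
  dep_g <- usage |>
    dplyr::filter(!(.data$codon %in% .STOP_CODONS)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(frac = sum(.data$count[.data$codon %in%
                                              model$dependent_codons]) /
                       sum(.data$count), .groups = "drop")
  r_g <- dep_g$frac[match(cds$gene_id, dep_g$gene_id)] /
    truth$dep_fraction_background

  beta <- setNames(rep(0, n), cds$gene_id)
  beta[names(truth$responders)] <- truth$responders

  i_bar <- truth$i_fractions |>
    dplyr::filter(.data$family_id %in% truth$subset_families) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(i_bar = mean(.data$i_fraction), .groups = "drop")
  i_bar <- setNames(i_bar$i_bar, i_bar$condition)

  abund <- rlnorm(n, meanlog = log(100), sdlog = 1)
  reps <- truth$replicates
  lib <- truth$library_size

  draw <- function(assay) {
    cols <- list()
    design <- list()
    for (cc in .CONDITIONS) {
      load <- if (assay == "rna") abund else
        abund * 2^(beta * i_bar[[cc]] * r_g)
      p <- load / sum(load)
      for (r in seq_len(reps)) {
        sid <- paste(assay, cc, r, sep = "_")
        cols[[sid]] <- as.integer(rmultinom(1, lib, p)[, 1])
        design[[sid]] <- tibble(sample_id = sid, assay = assay,
                                condition = cc, replicate = r)
      }
    }
    list(counts = dplyr::bind_cols(tibble(gene_id = cds$gene_id),
                                   as_tibble(cols)),
         design = dplyr::bind_rows(design))
  }
  rna <- draw("rna")
  ribo <- draw("ribo")
  list(rna = rna$counts, ribo = ribo$counts,
       design = dplyr::bind_rows(rna$design, ribo$design))
}

#' Simulate a tRNA-seq positional pileup at known inosine fractions
#'
#' Emits Sprinzl positions 33-35 for each family; at position 34 (reference
#' A) the G count is binomial in the true inosine fraction, with a small
#' sequencing-error rate diverted to C and T at every position.
#'
#' @param i_fractions Named numeric vector, `family_id` -> true inosine
#'   fraction in `[0, 1]`. Family ids must match
#'   `adat_codon_model()$families$family_id`.
#' @param depth Reads per position (default 2000).
#' @param error_rate Per-base error to each of C and T (default 0.001).
#' @param seed Optional seed (`NULL`: current stream).
#'
#' @return A pileup tibble (`family_id`, `sprinzl_pos`, `ref_base`,
#'   `count_A` ... `count_T`).
#' @export
simulate_pileups <- function(i_fractions, depth = 2000, error_rate = 0.001,
                             seed = NULL) {
  stopifnot(depth >= 1, all(i_fractions >= 0 & i_fractions <= 1))
  if (!is.null(seed)) set.seed(seed)
  fams <- adat_codon_model()$families
  unknown <- setdiff(names(i_fractions), fams$family_id)
  if (length(unknown) > 0) {
    adat_abort("invalid_configuration", paste0(
      "unknown tRNA family: ", paste(unknown, collapse = ", ")))
  }
  e <- error_rate
  rows <- lapply(names(i_fractions), function(fid) {
    ac <- fams$anticodon[fams$family_id == fid]
    f <- i_fractions[[fid]]
    refs <- c(`33` = "T", `34` = "A", `35` = substr(ac, 2, 2))
    dplyr::bind_rows(lapply(names(refs), function(pos) {
      if (pos == "34") {
        p <- c(A = (1 - f) * (1 - 2 * e), C = e, G = f * (1 - 2 * e), T = e)
      } else {
        p <- setNames(rep(e, 4), c("A", "C", "G", "T"))
        p[refs[[pos]]] <- 1 - 3 * e
      }
      cnt <- rmultinom(1, depth, p)[, 1]
      tibble(family_id = fid, sprinzl_pos = as.integer(pos),
             ref_base = refs[[pos]],
             count_A = cnt[["A"]], count_C = cnt[["C"]],
             count_G = cnt[["G"]], count_T = cnt[["T"]])
    }))
  })
  dplyr::bind_rows(rows)
}

#' Simulate a tumor/normal expression table
#'
#' Log-normal expression per gene and sample; overexpressed genes are
#' shifted up by `log2fc` in the tumor samples.
#'
#' @param gene_ids Gene universe.
#' @param overexpressed Genes shifted up in tumors.
#' @param n_tumor,n_normal Sample counts per group. Bundle defaults use 50
#'   per arm, the scale of the patient cohorts such screens draw on.
#' @param log2fc Planted tumor shift in log2 units (default 2).
#' @param seed Optional seed (`NULL`: current stream).
#' @return A tibble with `gene_id` and `tumor_*` / `normal_*` columns.
#' @export
simulate_tumor_table <- function(gene_ids, overexpressed = character(),
                                 n_tumor = 10, n_normal = 10, log2fc = 2,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(gene_ids)
  base <- rlnorm(n, meanlog = log(100), sdlog = 1)
  shift <- ifelse(gene_ids %in% overexpressed, 2^log2fc, 1)
  cols <- list()
  for (i in seq_len(n_tumor)) {
    cols[[paste0("tumor_", i)]] <- base * shift * rlnorm(n, 0, 0.5)
  }
  for (i in seq_len(n_normal)) {
    cols[[paste0("normal_", i)]] <- base * rlnorm(n, 0, 0.5)
  }
  dplyr::bind_cols(tibble(gene_id = gene_ids), as_tibble(cols))
}

#' Simulate a complete, ground-truthed multi-omic bundle
#'
#' One call generates gene-consistent inputs for every pipeline stage: CDS
#' with planted codon bias, RNA/Ribo counts under the codon-dependent
#' translation model, case/control tRNA pileups (ADAT2 overexpression vs.
#' its control), a tumor/normal table in which the planted responders are
#' overexpressed, and the truth record. Everything is drawn from a single
#' RNG stream seeded once, so regeneration with the same seed is
#' byte-identical.
#'
#' @param seed Integer seed for the whole bundle.
#' @param n_genes,length_codons,dep_fraction_background See
#'   [simulate_cds()].
#' @param n_responders Number of planted codon-biased TE responders
#'   (default 5).
#' @param responder_dep_fraction Dependent-codon target fraction of planted
#'   genes (default 0.30 vs. the 0.12 background, i.e. 2.5-fold enriched).
#' @param responder_effect Planted TE log2 effect size (default 1).
#' @param replicates Replicates per condition per assay (default 3).
#' @param library_size Reads per sample (default 1e6).
#' @param pileup_depth Reads per tRNA position (default 2000).
#' @param i_fractions Condition-wise inosine fractions
#'   (default [default_i_fractions()]).
#' @param subset_families tRNA families whose inosine supply drives the
#'   translation effect (default the three most ADAT2-responsive:
#'   Ser-AGA, Leu-AAG, Arg-ACG).
#' @param n_tumor,n_normal,tumor_log2fc See [simulate_tumor_table()].
#'
#' @return A `sim_bundle` list: `cds`, `rna`, `ribo`, `design`,
#'   `pileup_case`, `pileup_ctrl`, `tumor`, `truth` (the ground-truth
#'   record, including the planted responder set).
#' @export
simulate_bundle <- function(seed = 1, n_genes = 500, length_codons = 300,
                            dep_fraction_background = 0.12,
                            n_responders = 5, responder_dep_fraction = 0.30,
                            responder_effect = 1, replicates = 3,
                            library_size = 1e6, pileup_depth = 2000,
                            i_fractions = default_i_fractions(),
                            subset_families = c("Ser-AGA", "Leu-AAG",
                                                "Arg-ACG"),
                            n_tumor = 50, n_normal = 50, tumor_log2fc = 2) {
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  responders <- sort(sample(gene_ids, n_responders))
  planted <- setNames(rep(responder_dep_fraction, n_responders), responders)

  truth <- list(
    seed = seed,
    i_fractions = i_fractions,
    planted_biased_genes = planted,
    responders = setNames(rep(responder_effect, n_responders), responders),
    dep_fraction_background = dep_fraction_background,
    replicates = replicates,
    library_size = library_size,
    subset_families = subset_families
  )

  cds <- simulate_cds(n_genes, length_codons, dep_fraction_background,
                      planted = planted)
  counts <- simulate_counts(cds, truth)
  frac_of <- function(cond) {
    x <- i_fractions[i_fractions$condition == cond, ]
    setNames(x$i_fraction, x$family_id)
  }
  pileup_case <- simulate_pileups(frac_of("adat2_oe"), depth = pileup_depth)
  pileup_ctrl <- simulate_pileups(frac_of("control_oe"), depth = pileup_depth)
  tumor <- simulate_tumor_table(gene_ids, overexpressed = responders,
                                n_tumor = n_tumor, n_normal = n_normal,
                                log2fc = tumor_log2fc)

  structure(list(cds = cds, rna = counts$rna, ribo = counts$ribo,
                 design = counts$design, pileup_case = pileup_case,
                 pileup_ctrl = pileup_ctrl, tumor = tumor, truth = truth),
            class = "sim_bundle")
}

#' Write a simulated bundle to a directory
#'
#' Writes `cds.fa`, `rna.tsv`, `ribo.tsv`, `design.tsv`, `pileup_case.tsv`,
#' `pileup_ctrl.tsv`, `tumor.tsv` and `truth.json`. Output is deterministic
#' for a given bundle.
#'
#' @param bundle A `sim_bundle` from [simulate_bundle()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    cds = file.path(dir, "cds.fa"), rna = file.path(dir, "rna.tsv"),
    ribo = file.path(dir, "ribo.tsv"), design = file.path(dir, "design.tsv"),
    pileup_case = file.path(dir, "pileup_case.tsv"),
    pileup_ctrl = file.path(dir, "pileup_ctrl.tsv"),
    tumor = file.path(dir, "tumor.tsv"), truth = file.path(dir, "truth.json")
  )
  write_cds_fasta(bundle$cds, paths[["cds"]])
  write_tsv_det(bundle$rna, paths[["rna"]])
  write_tsv_det(bundle$ribo, paths[["ribo"]])
  write_tsv_det(bundle$design, paths[["design"]])
  write_tsv_det(bundle$pileup_case, paths[["pileup_case"]])
  write_tsv_det(bundle$pileup_ctrl, paths[["pileup_ctrl"]])
  write_tsv_det(bundle$tumor, paths[["tumor"]])
  jsonlite::write_json(bundle$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
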