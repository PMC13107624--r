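#' Configuration for an end-to-end pipeline run
#'
#' Bundles the input paths, output directory and the numeric settings of
#' every stage. Paths are checked at run time by [run_all()].
#'
#' @param cds,rna,ribo,design Input paths (FASTA / TSV; all required).
#' @param pileup_case,pileup_ctrl Optional tRNA pileup TSVs; when both are
#'   given the inosine stage runs.
#' @param tumor Optional tumor/normal TSV; when absent, funnel stage 3 is
#'   skipped with a flag.
#' @param out_dir Output directory.
#' @param bias_threshold,codon_subset,oe_alpha,ranking_key See
#'   [funnel_config()].
#' @param pseudocount_te,min_abs_log2fc See [translation_efficiency()].
#' @param pseudocount_inosine,min_coverage See [estimate_inosine()] and
#'   [inosine_fold_change()].
#' @param seed Optional integer recorded in the manifest and set before the
#'   run (the analysis itself is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cds, rna, ribo, design,
                            pileup_case = NULL, pileup_ctrl = NULL,
                            tumor = NULL, out_dir = ".",
                            bias_threshold = 1.5,
                            codon_subset = c("TCC", "CTC", "CGC"),
                            oe_alpha = 0.05,
                            ranking_key = "fold_enrichment",
                            pseudocount_te = 0.5, min_abs_log2fc = 0,
                            pseudocount_inosine = 0.01, min_coverage = 100,
                            seed = NULL) {
  cfg <- list(cds = cds, rna = rna, ribo = ribo, design = design,
              pileup_case = pileup_case, pileup_ctrl = pileup_ctrl,
              tumor = tumor, out_dir = out_dir,
              bias_threshold = bias_threshold, codon_subset = codon_subset,
              oe_alpha = oe_alpha, ranking_key = ranking_key,
              pseudocount_te = pseudocount_te,
              min_abs_log2fc = min_abs_log2fc,
              pseudocount_inosine = pseudocount_inosine,
              min_coverage = min_coverage, seed = seed)
  # validate numeric settings early
  funnel_config(bias_threshold, codon_subset, oe_alpha,
                match.arg(ranking_key, c("fold_enrichment", "log2fc_te_oe")))
  stopifnot(pseudocount_te > 0, pseudocount_inosine > 0, min_coverage >= 1,
            min_abs_log2fc >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    adat_abort("io", paste0("config file not found: ", path))
  }
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
          class = c("adatscan_stage_error", "adatscan_error"), parent = e)
  })
}

#' Run the whole screen end to end
#'
#' Reads the inputs, then executes: inosine quantification (if pileups are
#' configured), CPM normalization + translation efficiency + concordance,
#' codon-usage-bias scoring against the supplied CDS background, and the
#' three-stage candidate funnel. Writes `inosine.tsv` (when run),
#' `te.tsv`, `bias.tsv`, `funnel.tsv`, `report.txt` and `manifest.json`
#' (package version, seed, configuration and its hash, stage counts) to the
#' output directory. A failure in any stage aborts with the stage name and
#' cause.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the `adat_funnel` result.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (p in c("cds", "rna", "ribo", "design")) {
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]])) {
      adat_abort("io", paste0("required input '", p, "' not found: ",
                              cfg[[p]] %||% "<missing>"))
    }
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  model <- adat_codon_model(cfg$codon_subset)

  inosine <- NULL
  if (!is.null(cfg$pileup_case) && !is.null(cfg$pileup_ctrl)) {
    inosine <- run_stage("inosine_quant", {
      est_case <- estimate_inosine(read_pileup_tsv(cfg$pileup_case),
                                   min_coverage = cfg$min_coverage)
      est_ctrl <- estimate_inosine(read_pileup_tsv(cfg$pileup_ctrl),
                                   min_coverage = cfg$min_coverage)
      fc <- inosine_fold_change(est_case, est_ctrl,
                                pseudocount = cfg$pseudocount_inosine)
      write_tsv_det(est_case, file.path(cfg$out_dir, "inosine_case.tsv"))
      write_tsv_det(est_ctrl, file.path(cfg$out_dir, "inosine_ctrl.tsv"))
      write_tsv_det(fc, file.path(cfg$out_dir, "inosine.tsv"))
      fc
    })
  }

  te <- run_stage("translation_metrics", {
    out <- translation_efficiency(read_counts_tsv(cfg$rna),
                                  read_counts_tsv(cfg$ribo),
                                  read_design_tsv(cfg$design),
                                  pseudocount = cfg$pseudocount_te,
                                  min_abs_log2fc = cfg$min_abs_log2fc)
    write_tsv_det(out, file.path(cfg$out_dir, "te.tsv"))
    out
  })

  bias <- run_stage("codon_analysis", {
    cds <- read_cds_fasta(cfg$cds)
    out <- codon_bias(cds, model, threshold = cfg$bias_threshold)
    write_tsv_det(out, file.path(cfg$out_dir, "bias.tsv"))
    out
  })

  funnel <- run_stage("candidate_funnel", {
    tumor <- if (!is.null(cfg$tumor)) read_tumor_tsv(cfg$tumor)
    fc <- funnel_config(cfg$bias_threshold, cfg$codon_subset, cfg$oe_alpha,
                        cfg$ranking_key)
    res <- run_funnel(te, bias, tumor = tumor, config = fc)
    rep <- funnel_report(res)
    write_tsv_det(rep$table, file.path(cfg$out_dir, "funnel.tsv"))
    writeLines(rep$text, file.path(cfg$out_dir, "report.txt"))
    res
  })

  manifest <- list(
    package = "adatscan",
    version = as.character(utils::packageVersion("adatscan")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    inosine_stage_run = !is.null(inosine),
    stage_counts = list(stage1 = length(funnel$stage1),
                        stage2 = length(funnel$stage2),
                        stage3 = length(funnel$stage3)),
    tumor_filter_applied = funnel$tumor_filter_applied
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(funnel)
}
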