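test_that("the toy funnel reproduces brute-force stage membership (4/2/1)", {
  inp <- toy_funnel_inputs()
  res <- run_funnel(inp$te, inp$bias, tumor = inp$tumor)
  oracle <- toy_funnel_oracle(inp)
  expect_equal(res$stage1, oracle$stage1)
  expect_equal(res$stage2, oracle$stage2)
  expect_equal(res$stage3, oracle$stage3)
  expect_equal(lengths(oracle[c("stage1", "stage2", "stage3")]),
               c(stage1 = 4L, stage2 = 2L, stage3 = 1L))
  # nesting invariant
  expect_true(all(res$stage3 %in% res$stage2))
  expect_true(all(res$stage2 %in% res$stage1))
})

test_that("funnel output is byte-identical across runs", {
  inp <- toy_funnel_inputs()
  paths <- replicate(2, {
    res <- run_funnel(inp$te, inp$bias, tumor = inp$tumor)
    p <- tempfile(fileext = ".tsv")
    readr::write_tsv(funnel_report(res)$table, p)
    p
  })
  expect_identical(readBin(paths[1], "raw", file.size(paths[1])),
                   readBin(paths[2], "raw", file.size(paths[2])))
})

test_that("a zero bias threshold is vacuous and higher thresholds nest", {
  inp <- toy_funnel_inputs()
  res0 <- run_funnel(inp$te, inp$bias,
                     config = funnel_config(bias_threshold = 0))
  expect_equal(res0$stage2, res0$stage1)

  sizes <- vapply(seq(1, 2, by = 0.25), function(th) {
    length(run_funnel(inp$te, inp$bias,
                      config = funnel_config(bias_threshold = th))$stage2)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("without a tumor table stage3 equals stage2 and is flagged", {
  inp <- toy_funnel_inputs()
  res <- run_funnel(inp$te, inp$bias)
  expect_equal(res$stage3, res$stage2)
  expect_false(res$tumor_filter_applied)
  expect_match(paste(funnel_report(res)$text, collapse = "\n"), "skipped")
})

test_that("concordant genes without a bias score are dropped with a warning", {
  inp <- toy_funnel_inputs()
  bias <- inp$bias[inp$bias$gene_id != "t01", ]
  expect_warning(res <- run_funnel(inp$te, bias, tumor = inp$tumor),
                 class = "adatscan_incomplete_evidence")
  expect_false("t01" %in% res$stage1)
  expect_equal(res$dropped$gene_id, "t01")
  expect_equal(res$dropped$reason, "missing bias score")
})

test_that("candidates rank by the key, descending, ties lexicographic", {
  inp <- toy_funnel_inputs()
  # make t02 overexpressed too, and tie its fold with t01
  inp$tumor$overexpressed[inp$tumor$gene_id == "t02"] <- TRUE
  inp$bias$fold_enrichment[inp$bias$gene_id == "t02"] <- 2.0
  res <- run_funnel(inp$te, inp$bias, tumor = inp$tumor)
  expect_equal(res$ranked_candidates, c("t01", "t02"))
  expect_setequal(res$ranked_candidates, res$stage3)
})

test_that("disjoint gene universes abort; empty stages report zeros", {
  inp <- toy_funnel_inputs()
  bias_other <- dplyr::mutate(inp$bias, gene_id = paste0("x", gene_id))
  expect_error(run_funnel(inp$te, bias_other), class = "adatscan_no_overlap")

  te_none <- dplyr::mutate(inp$te, concordant = FALSE)
  res <- run_funnel(te_none, inp$bias, tumor = inp$tumor)
  expect_equal(length(res$stage1), 0L)
  rep <- funnel_report(res)
  expect_match(rep$text[2], "stage1_concordant\t0")
  expect_equal(nrow(rep$table), 10L)   # one row per universe gene
})

test_that("tidy and glance summarize the funnel object", {
  inp <- toy_funnel_inputs()
  res <- run_funnel(inp$te, inp$bias, tumor = inp$tumor)
  td <- tidy(res)
  expect_equal(nrow(td), 10L)
  expect_equal(td$stage_reached[td$gene_id == "t01"], 3)
  expect_equal(td$stage_reached[td$gene_id == "t10"], 0)
  gl <- glance(res)
  expect_equal(gl$n_stage1, 4L)
  expect_equal(gl$n_stage2, 2L)
  expect_equal(gl$n_stage3, 1L)
})

test_that("overexpression calls support all three evidence shapes", {
  # precomputed flag
  x <- tibble::tibble(gene_id = c("a", "b"), overexpressed = c(TRUE, FALSE))
  expect_equal(call_overexpression(x)$overexpressed, c(TRUE, FALSE))
  # means only: direction rule
  y <- tibble::tibble(gene_id = c("a", "b"),
                      mean_tumor = c(10, 5), mean_normal = c(5, 10))
  expect_equal(call_overexpression(y)$overexpressed, c(TRUE, FALSE))
  # per-sample: rank-sum + BH
  set.seed(2)
  genes <- sprintf("g%02d", 1:40)
  tab <- simulate_tumor_table(genes, overexpressed = genes[1:4],
                              n_tumor = 30, n_normal = 30, log2fc = 3)
  oc <- call_overexpression(tab)
  expect_true(all(oc$overexpressed[1:4]))
  expect_lt(sum(oc$overexpressed[-(1:4)]), 3)
  # unusable shape
  expect_error(call_overexpression(tibble::tibble(gene_id = "a", z = 1)),
               class = "adatscan_invalid_tumor_table")
})
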