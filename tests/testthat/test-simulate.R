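test_that("generators are byte-deterministic under a fixed seed", {
  b1 <- simulate_bundle(seed = 21, n_genes = 30, length_codons = 40,
                        library_size = 2e4, pileup_depth = 300,
                        n_tumor = 5, n_normal = 5)
  b2 <- simulate_bundle(seed = 21, n_genes = 30, length_codons = 40,
                        library_size = 2e4, pileup_depth = 300,
                        n_tumor = 5, n_normal = 5)
  expect_identical(b1$cds, b2$cds)
  expect_identical(b1$rna, b2$rna)
  expect_identical(b1$pileup_case, b2$pileup_case)
  expect_identical(b1$tumor, b2$tumor)

  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("CDS generation honors planted dependent-codon fractions", {
  model <- adat_codon_model()
  # zero target -> no dependent codons at all
  cds0 <- simulate_cds(1, length_codons = 50,
                       planted = c(g0001 = 0), seed = 31)
  u0 <- codon_usage(cds0)
  expect_equal(sum(u0$count[u0$codon %in% model$dependent_codons]), 0L)

  # 0.4 target at 300 codons: realized within +/- 3 binomial SD
  cds4 <- simulate_cds(1, length_codons = 300,
                       planted = c(g0001 = 0.4), seed = 32)
  u4 <- codon_usage(cds4)
  keep <- !(u4$codon %in% c("TAA", "TAG", "TGA"))
  frac <- sum(u4$count[keep & u4$codon %in% model$dependent_codons]) /
    sum(u4$count[keep])
  expect_gt(frac, 0.33)
  expect_lt(frac, 0.47)

  # structural guarantees
  expect_match(cds4$sequence, "^ATG")
  expect_match(cds4$sequence, "TAA$")
  body <- substr(cds4$sequence, 1, nchar(cds4$sequence) - 3)
  cod <- substring(body, seq(1, nchar(body), 3), seq(3, nchar(body), 3))
  expect_false(any(cod %in% c("TAA", "TAG", "TGA")))

  # infeasible target
  expect_error(simulate_cds(1, planted = c(g0001 = 0.5)),
               class = "adatscan_infeasible_fraction")
})

test_that("pileup simulation matches its binomial truth", {
  fams <- adat_codon_model()$families$family_id
  p1 <- simulate_pileups(setNames(1, fams[1]), depth = 100, seed = 33)
  at34 <- p1[p1$sprinzl_pos == 34, ]
  expect_lte(at34$count_A, 1)   # fully modified: essentially no A left

  p5 <- simulate_pileups(setNames(0.5, fams[2]), depth = 1e4, seed = 34)
  est <- estimate_inosine(p5)
  expect_lt(abs(est$i_fraction - 0.5), 0.02)

  expect_error(simulate_pileups(c(nope = 0.5)),
               class = "adatscan_invalid_configuration")
})

test_that("zero planted effect leaves expected TE flat across conditions", {
  b <- simulate_bundle(seed = 35, n_genes = 100, length_codons = 80,
                       responder_effect = 0, library_size = 5e5)
  te <- translation_efficiency(b$rna, b$ribo, b$design)
  # no systematic shift: mean log2 FC across genes is ~0
  expect_lt(abs(mean(te$log2fc_te_oe)), 0.02)
  expect_lt(abs(mean(te$log2fc_te_ko)), 0.02)
})

test_that("a planted responder has positive expected OE TE response", {
  b <- simulate_bundle(seed = 36, n_genes = 100, length_codons = 80,
                       n_responders = 1, responder_effect = 1,
                       library_size = 1e6)
  te <- translation_efficiency(b$rna, b$ribo, b$design)
  resp <- names(b$truth$responders)
  expect_gt(te$log2fc_te_oe[te$gene_id == resp], 0)
  expect_lt(te$log2fc_te_ko[te$gene_id == resp], 0)
})

test_that("families with a planted inosine gain rank top by fold change", {
  fams <- adat_codon_model()$families$family_id
  boosted <- c("Ser-AGA", "Leu-AAG", "Arg-ACG")
  ctrl_f <- setNames(rep(0.5, 8), fams)
  case_f <- ctrl_f
  case_f[boosted] <- 0.7
  set.seed(37)
  case <- estimate_inosine(simulate_pileups(case_f, depth = 2000))
  ctrl <- estimate_inosine(simulate_pileups(ctrl_f, depth = 2000))
  fc <- inosine_fold_change(case, ctrl)
  expect_setequal(fc$family_id[1:3], boosted)
})
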