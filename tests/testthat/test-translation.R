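make_counts <- function(genes, ...) {
  tibble::tibble(gene_id = genes, ...)
}

# minimal matched design: one sample per condition per assay
flat_design <- function(reps = 1) {
  conds <- c("control_oe", "adat2_oe", "control_ko", "adat2_ko")
  do.call(rbind, lapply(c("rna", "ribo"), function(a) {
    do.call(rbind, lapply(conds, function(cc) {
      data.frame(sample_id = paste(a, cc, seq_len(reps), sep = "_"),
                 assay = a, condition = cc, replicate = seq_len(reps))
    }))
  }))
}

test_that("CPM normalization conserves and is scale invariant", {
  x <- make_counts(c("a", "b"), s1 = c(10, 0))
  expect_equal(cpm_normalize(x)$s1, c(1e6, 0))

  y <- make_counts(c("a", "b", "c"), s1 = c(5, 10, 35), s2 = c(1, 2, 7))
  cy <- cpm_normalize(y)
  expect_equal(cy$s1, cy$s2)           # doubling-invariance across columns
  expect_equal(colSums(as.matrix(cy[, -1])), c(s1 = 1e6, s2 = 1e6))

  z <- make_counts(c("a", "b"), s1 = c(0, 0))
  expect_error(cpm_normalize(z), class = "adatscan_degenerate_sample")
})

test_that("TE is the pseudocounted ribo/rna CPM ratio", {
  genes <- c("a", "b")
  des <- flat_design()
  rna <- make_counts(genes)
  ribo <- make_counts(genes)
  for (s in des$sample_id[des$assay == "rna"]) rna[[s]] <- c(100, 100)
  for (s in des$sample_id[des$assay == "ribo"]) ribo[[s]] <- c(200, 100)
  te <- translation_efficiency(rna, ribo, des, pseudocount = 1e-6)
  # rna CPM a = 5e5; ribo CPM a = 2/3 * 1e6 -> TE = 4/3
  expect_equal(te$te_control_oe[te$gene_id == "a"], (2 / 3 * 1e6) / 5e5,
               tolerance = 1e-6)
  # identical conditions: zero fold changes, nothing concordant
  expect_equal(te$log2fc_te_oe, c(0, 0))
  expect_false(any(te$concordant))
})

test_that("TE is invariant to scaling one sample's library", {
  b <- simulate_bundle(seed = 3, n_genes = 40, length_codons = 60,
                       library_size = 5e4)
  te1 <- translation_efficiency(b$rna, b$ribo, b$design)
  rna2 <- b$rna
  rna2$rna_adat2_oe_1 <- rna2$rna_adat2_oe_1 * 7L
  te2 <- translation_efficiency(rna2, b$ribo, b$design)
  expect_equal(te2$te_adat2_oe, te1$te_adat2_oe)
})

test_that("swapping the OE condition with its control negates the log2 FC", {
  b <- simulate_bundle(seed = 4, n_genes = 40, length_codons = 60,
                       library_size = 5e4)
  te1 <- translation_efficiency(b$rna, b$ribo, b$design)
  des2 <- b$design
  des2$condition[des2$condition == "adat2_oe"] <- "tmp"
  des2$condition[des2$condition == "control_oe"] <- "adat2_oe"
  des2$condition[des2$condition == "tmp"] <- "control_oe"
  te2 <- translation_efficiency(b$rna, b$ribo, des2)
  expect_equal(te2$log2fc_te_oe, -te1$log2fc_te_oe)
})

test_that("a missing condition is an unmatched-design error", {
  b <- simulate_bundle(seed = 5, n_genes = 20, length_codons = 60,
                       library_size = 2e4)
  des <- b$design[b$design$condition != "adat2_ko", ]
  expect_error(translation_efficiency(b$rna, b$ribo, des),
               class = "adatscan_unmatched_design")
  bad <- b$design
  bad$condition[1] <- "mystery"
  expect_error(translation_efficiency(b$rna, b$ribo, bad),
               class = "adatscan_invalid_design")
})

test_that("planted concordant responders are recovered from deep data", {
  b <- simulate_bundle(seed = 8, n_responders = 20)
  te <- translation_efficiency(b$rna, b$ribo, b$design)
  resp <- names(b$truth$responders)
  recovered <- sum(te$concordant[te$gene_id %in% resp])
  expect_gte(recovered, 18)
})

test_that("null concordance matches the correlated sign-agreement rate", {
  # With zero planted effect each gene's four log-FCs are pure noise, but
  # TE and Ribo FCs share the Ribo term (correlation 1/sqrt(2)), so
  # P(concordant | null) = (3/8)^2 = 9/64, not the 1/16 of four
  # independent signs.
  b <- simulate_bundle(seed = 9, responder_effect = 0)
  te <- translation_efficiency(b$rna, b$ribo, b$design)
  rate <- mean(te$concordant)
  p0 <- 9 / 64
  se <- sqrt(p0 * (1 - p0) / nrow(te))
  expect_lt(abs(rate - p0), 4 * se)
})

test_that("polysome fractions map to the three translational states", {
  expect_equal(classify_polysome_fraction("80S"), "initiation")
  expect_equal(classify_polysome_fraction("sub40S"), "untranslated")
  expect_equal(classify_polysome_fraction("polysome"), "active")
  expect_equal(classify_polysome_fraction(c("40S", "60S")),
               c("initiation", "initiation"))
  expect_error(classify_polysome_fraction("90S"),
               class = "adatscan_invalid_label")
})
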