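test_that("the mismatch estimator recovers boundary fractions exactly", {
  e <- estimate_inosine(pileup_row(A = 50, G = 50), min_coverage = 10)
  expect_equal(e$i_fraction, 0.5)
  expect_equal(e$i_to_a_ratio, 1.0)
  expect_equal(e$coverage, 100L)
  expect_false(e$flag_low_coverage)

  e0 <- estimate_inosine(pileup_row(A = 100, G = 0), min_coverage = 10)
  expect_equal(e0$i_fraction, 0)
  expect_equal(e0$i_to_a_ratio, 0)

  # fully modified: ratio is infinite, fraction 1
  e1 <- estimate_inosine(pileup_row(A = 0, G = 200), min_coverage = 10)
  expect_equal(e1$i_fraction, 1)
  expect_true(is.infinite(e1$i_to_a_ratio))
})

test_that("C/T reads count toward coverage but not the fraction", {
  e <- estimate_inosine(pileup_row(A = 40, C = 10, G = 40, T = 10),
                        min_coverage = 10)
  expect_equal(e$i_fraction, 0.5)
  expect_equal(e$coverage, 100L)
})

test_that("malformed pileups fail with named families", {
  # no position 34
  expect_error(estimate_inosine(pileup_row(pos = 35, ref = "G")),
               class = "adatscan_malformed_pileup")
  # reference base at 34 is not A
  expect_error(estimate_inosine(pileup_row(ref = "G", G = 100)),
               class = "adatscan_family_mismatch")
  expect_error(estimate_inosine(pileup_row(A = -1)),
               class = "adatscan_malformed_pileup")
})

test_that("the estimator is calibrated under binomial sampling", {
  set.seed(77)
  truth <- 0.7
  ests <- replicate(50, {
    g <- rbinom(1, 2000, truth)
    estimate_inosine(pileup_row(A = 2000 - g, G = g))$i_fraction
  })
  expect_lt(abs(mean(ests) - truth), 0.02)
})

test_that("fold changes are antisymmetric under case/control swap", {
  set.seed(5)
  fams <- adat_codon_model()$families$family_id
  case <- estimate_inosine(simulate_pileups(
    setNames(runif(8, 0.3, 0.9), fams), depth = 1000))
  ctrl <- estimate_inosine(simulate_pileups(
    setNames(runif(8, 0.3, 0.9), fams), depth = 1000))
  fwd <- inosine_fold_change(case, ctrl, pseudocount = 0.01)
  rev <- inosine_fold_change(ctrl, case, pseudocount = 0.01)
  rev <- rev[match(fwd$family_id, rev$family_id), ]
  expect_equal(fwd$log2_fold_change, -rev$log2_fold_change)
})

test_that("identical case and control give unit folds", {
  e <- estimate_inosine(pileup_row(A = 60, G = 140))
  fc <- inosine_fold_change(e, e)
  expect_equal(fc$fold_change, 1.0)
  expect_equal(fc$log2_fold_change, 0.0)
})

test_that("low-coverage families never reach the fold-change table", {
  ok <- pileup_row(family_id = "Ser-AGA", A = 500, G = 500)
  low <- pileup_row(family_id = "Leu-AAG", A = 5, G = 5)
  est <- estimate_inosine(dplyr::bind_rows(ok, low), min_coverage = 100)
  expect_true(est$flag_low_coverage[est$family_id == "Leu-AAG"])
  fc <- inosine_fold_change(est, est)
  expect_equal(fc$family_id, "Ser-AGA")

  only_low <- estimate_inosine(low, min_coverage = 100)
  expect_error(inosine_fold_change(only_low, only_low),
               class = "adatscan_no_common_family")
})

test_that("the pseudocount-free limit reproduces the ratio of ratios", {
  case <- estimate_inosine(pileup_row(A = 1000, G = 2000))   # ratio 2.0
  ctrl <- estimate_inosine(pileup_row(A = 2000, G = 1000))   # ratio 0.5
  fc <- inosine_fold_change(case, ctrl, pseudocount = 1e-9)
  expect_equal(fc$fold_change, 4.0, tolerance = 1e-6)
})
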