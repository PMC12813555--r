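test_that("allele alignment joins, flips and drops as specified", {
  ref <- data.table::data.table(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "A", "A", "A"),
    other_allele = c("C", "C", "T", "C"),
    beta = c(0.1, 0.2, 0.3, 0.4), se = 0.05, p = 0.5)
  study <- data.table::copy(ref)
  # identical files: full join, no flips
  al <- align_variants(study, ref)
  expect_equal(nrow(al$table), 3)           # rs3 is A/T ambiguous
  expect_equal(al$n_dropped_ambiguous, 1)
  expect_false(any(al$table$flipped))
  expect_identical(al$table$beta_study, al$table$beta_ref)
  # swapped alleles: beta negated
  study2 <- data.table::copy(ref)
  study2[variant_id == "rs2", `:=`(effect_allele = "C", other_allele = "A")]
  al2 <- align_variants(study2, ref)
  expect_equal(al2$table[variant_id == "rs2"]$beta_study, -0.2)
  expect_true(al2$table[variant_id == "rs2"]$flipped)
  # mismatched allele pair dropped and counted
  study3 <- data.table::copy(ref)
  study3[variant_id == "rs4", `:=`(effect_allele = "G", other_allele = "T")]
  al3 <- align_variants(study3, ref)
  expect_equal(al3$n_dropped_mismatch, 1)
  expect_false("rs4" %in% al3$table$variant_id)
})

test_that("self-dilution is exactly one", {
  set.seed(17)
  pair <- sim_sumstats_pair(m = 200, delta = 1)
  d <- estimate_dilution(pair$ref, pair$ref, n_boot = 200, seed = 1)
  expect_identical(d$delta_hat, 1)
  expect_true(all(abs(d$ci95 - 1) < 1e-12))
})

test_that("a constructed half-scale study recovers dilution two", {
  set.seed(18)
  b <- rnorm(500, 0, 0.05)
  mk <- function(beta) data.table::data.table(
    variant_id = sprintf("rs%d", 1:500), effect_allele = "A",
    other_allele = "C", beta = beta, se = 0.01, p = 0.5)
  d <- estimate_dilution(mk(b / 2 + rnorm(500, 0, 1e-5)), mk(b),
                         n_boot = 200, seed = 2)
  expect_equal(d$delta_hat, 2, tolerance = 0.01)
  expect_true(d$ci95[1] <= 2 && 2 <= d$ci95[2])
  expect_lt(d$p_vs_1, 0.05)
})

test_that("dilution is deterministic, order-invariant and near-reciprocal", {
  set.seed(19)
  pair <- sim_sumstats_pair(m = 1000, delta = 1.25)
  d1 <- estimate_dilution(pair$study, pair$ref, n_boot = 300, seed = 5)
  d2 <- estimate_dilution(pair$study, pair$ref, n_boot = 300, seed = 5)
  expect_identical(d1$delta_hat, d2$delta_hat)
  expect_identical(d1$ci95, d2$ci95)
  shuf <- pair$study[sample(.N)]
  d3 <- estimate_dilution(shuf, pair$ref, n_boot = 300, seed = 5)
  expect_equal(d3$delta_hat, d1$delta_hat, tolerance = 1e-12)
  # reciprocal within bootstrap tolerance (regression dilution adds bias
  # of order (se/beta_sd)^2, small here)
  dba <- estimate_dilution(pair$ref, pair$study, n_boot = 300, seed = 5)
  expect_equal(dba$delta_hat, 1 / d1$delta_hat, tolerance = 0.15)
})

test_that("degenerate inputs error as specified", {
  set.seed(20)
  pair <- sim_sumstats_pair(m = 30)
  expect_error(estimate_dilution(pair$study, pair$ref), "aligned variants")
  # orthogonal noise: no shared signal
  a <- data.table::data.table(variant_id = sprintf("rs%d", 1:100),
                              effect_allele = "A", other_allele = "C",
                              beta = rep(c(1, -1), 50), se = 0.1, p = 0.5)
  b <- data.table::copy(a)
  b$beta <- rep(c(-1, 1), 50)
  expect_error(estimate_dilution(a, b, n_boot = 50), "no shared signal")
})
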