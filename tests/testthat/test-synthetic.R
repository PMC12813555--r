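cfg <- cohort_config()

test_that("realized prescription patterns round-trip through the classifier", {
  span <- c(0, 7300)
  set.seed(1)
  expect_identical(realize_exposure_pattern("none", span), integer(0))
  for (i in 1:1000) {
    expect_length(realize_exposure_pattern("single", span), 1L)
    d_min <- realize_exposure_pattern("minimal", span)
    expect_length(d_min, 2L)
    expect_true(diff(d_min) >= 1 && diff(d_min) <= 90)
    expect_identical(classify_exposure(d_min, cfg), "minimal")
    d_chr <- realize_exposure_pattern("chronic", span)
    expect_gte(length(d_chr), 3L)
    expect_true(all(diff(d_chr) < 90))
    expect_identical(classify_exposure(d_chr, cfg), "chronic_pattern")
  }
  expect_error(realize_exposure_pattern("minimal", c(0, 600)), "two years")
})

test_that("genotype simulation matches its binomial model", {
  set.seed(2)
  g <- simulate_genotypes(10000, 50, maf_range = c(0.5, 0.5))
  expect_true(all(g$dosages %in% 0:2))
  expect_true(all(abs(colMeans(g$dosages) - 1) < 0.04))
  expect_true(all(g$obs_freq > 0 & g$obs_freq < 1))
  expect_true(all(g$effect_allele != g$other_allele))
  expect_error(simulate_genotypes(10, 0), "m must be")
  expect_error(simulate_genotypes(10, 5, maf_range = c(0.6, 0.7)), "maf_range")
  set.seed(9); a <- simulate_genotypes(50, 10)
  set.seed(9); b <- simulate_genotypes(50, 10)
  expect_identical(a, b)
})

test_that("liability-threshold phenotype hits its prevalence and null model", {
  set.seed(3)
  g <- simulate_genotypes(20000, 100)
  ph <- simulate_liability_phenotype(g, case_prevalence = 0.2,
                                     n_causal = 20, heritability_liability = 0.5)
  expect_true(abs(mean(ph$case) - 0.2) < 0.01)
  # null heritability: case status independent of any single variant
  ph0 <- simulate_liability_phenotype(g, 0.2, n_causal = 20,
                                      heritability_liability = 0)
  r <- abs(cor(g$dosages[, 1], ph0$case))
  expect_lt(r, 0.02)
  # causal variants carry more association signal than null variants
  z2 <- function(j, case) {
    f <- fit_logistic_assoc(case, g$dosages[, j] > 0)
    (f$beta / f$se)^2
  }
  z_causal <- vapply(1:20, z2, numeric(1), case = ph$case)
  z_null <- vapply(81:100, z2, numeric(1), case = ph$case)
  expect_gt(mean(z_causal), mean(z_null))
  expect_error(simulate_liability_phenotype(g, 0.2, 20, 1.5), "heritability")
})

test_that("generator is deterministic, seed-sensitive, and respects degenerate strata", {
  cfg_small <- generator_config(n_patients = 500, n_variants = 20, n_causal = 5,
                                seed = 11)
  a <- generate_dataset(cfg_small)
  b <- generate_dataset(cfg_small)
  expect_identical(a$dataset$diagnoses, b$dataset$diagnoses)
  expect_identical(a$dataset$prescriptions, b$dataset$prescriptions)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  cfg2 <- generator_config(n_patients = 500, n_variants = 20, n_causal = 5,
                           seed = 12)
  c <- generate_dataset(cfg2)
  expect_false(identical(a$dataset$prescriptions, c$dataset$prescriptions))
  # zero prevalence: nobody carries an OUD code
  cfg0 <- generator_config(n_patients = 300, case_prevalence = 0,
                           n_variants = 20, n_causal = 5, seed = 1)
  d0 <- generate_dataset(cfg0)
  expect_false(any(normalize_icd(d0$dataset$diagnoses$code) %in% cohort_config()$oud_codes))
  expect_false(any(d0$truth$is_case))
})

test_that("generated patients satisfy their intended floor and exposure labels", {
  gen <- generate_dataset(generator_config(n_patients = 3000, n_variants = 20,
                                           n_causal = 5, seed = 21))
  fl <- oudcontrols:::patient_flags(gen$dataset, cfg)
  tr <- gen$truth
  expect_identical(fl$exposure_class, tr$exposure_class)
  expect_identical(fl$floor, tr$floor_intent_pass)
  # dataset invariants: events inside [birth, end], ids known
  expect_s3_class(gen$dataset, "ehr_dataset")
})

test_that("stratum frequencies and comorbidity odds ratios are calibrated", {
  specs <- list(comorbidity_spec("777.00", prevalence = 0.10,
                                 log_or_case = log(3)))
  gen <- generate_dataset(generator_config(
    n_patients = 50000, case_prevalence = 0.1, comorbidity_specs = specs,
    n_variants = 0, seed = 5))
  tr <- gen$truth
  # exposure-class frequencies within binomial tolerance per stratum
  probs <- generator_config()$exposure_class_probs$noncase
  tab <- prop.table(table(tr$exposure_class[!tr$is_case]))
  lab <- c(none = "unexposed", single = "single_rx", minimal = "minimal",
           chronic = "chronic_pattern")
  for (k in names(probs)) {
    expect_lt(abs(tab[[lab[[k]]]] - probs[[k]]),
              3 * sqrt(probs[[k]] * (1 - probs[[k]]) / sum(!tr$is_case)) + 1e-3)
  }
  # empirical 2x2 OR inside the 95% CI of the configured OR
  stripped <- "77700"
  pos <- unique(gen$dataset$diagnoses[code %in% c(paste0("Y", stripped),
                                                  paste0("V", stripped))]$patient_id)
  phe <- tr$patient_id %in% pos
  fit <- fit_logistic_assoc(phe, tr$is_case)
  expect_true(fit$ci_lo < 3 && 3 < fit$ci_hi)
})

test_that("impossible comorbidity specs are rejected naming the phecode", {
  expect_error(comorbidity_spec("123.45", prevalence = 1.2, log_or_case = 1),
               "123\\.45")
  expect_error(comorbidity_spec("123.45", prevalence = 0, log_or_case = 1),
               "123\\.45")
})

test_that("dataset validation rejects inconsistent tables", {
  ds <- toy_dataset()
  bad_dx <- data.table::copy(ds$diagnoses)
  bad_dx$patient_id[1] <- 999L
  expect_error(new_ehr_dataset(ds$patients, bad_dx, ds$prescriptions, 7300L),
               "unknown patient ids")
  bad_dx2 <- data.table::copy(ds$diagnoses)
  bad_dx2$event_date[1] <- 9000L
  expect_error(new_ehr_dataset(ds$patients, bad_dx2, ds$prescriptions, 7300L),
               "outside")
})
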