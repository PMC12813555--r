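cfg <- cohort_config()

test_that("case and cancer code checks match their definitions", {
  expect_false(is_case(character(0), cfg$oud_codes))
  expect_true(is_case("F11.20", cfg$oud_codes))          # dotted dialect
  expect_true(is_case(rep("f1120", 5), cfg$oud_codes))   # idempotent, case-folded
  expect_false(is_case(c("R99", "C50.9"), cfg$oud_codes))
  expect_false(has_cancer(character(0), cfg$cancer_codes))
  expect_true(has_cancer("C50.9", cfg$cancer_codes))
  expect_false(has_cancer(c("R99", "F11.20"), cfg$cancer_codes))
})

test_that("data floor requires five distinct days inside one 3-year window", {
  expect_true(meets_data_floor(c(0, 1, 2, 3, 4), cfg))
  expect_false(meets_data_floor(c(0, 400, 800, 1200, 1600), cfg))
  expect_false(meets_data_floor(rep(0, 5), cfg))
  # boundary: five days spanning exactly the window length pass
  expect_true(meets_data_floor(c(0, 1, 2, 3, 1095), cfg))
  expect_false(meets_data_floor(c(0, 1, 2, 3, 1096), cfg))
})

test_that("data floor agrees with a literal window sweep and is monotone", {
  set.seed(42)
  for (i in 1:400) {
    d <- sample(0:4000, sample(1:10, 1), replace = TRUE)
    expect_identical(meets_data_floor(d, cfg), brute_floor(d))
    if (meets_data_floor(d, cfg)) {
      expect_true(meets_data_floor(c(d, sample(0:4000, 1)), cfg))
    }
  }
})

test_that("exposure classifier reproduces the worked rule examples", {
  expect_identical(classify_exposure(integer(0), cfg), "unexposed")
  expect_identical(classify_exposure(500, cfg), "single_rx")
  expect_identical(classify_exposure(c(0, 50), cfg), "minimal")
  expect_identical(classify_exposure(c(0, 90), cfg), "minimal")   # <= boundary
  expect_identical(classify_exposure(c(0, 91), cfg), "other")
  expect_identical(classify_exposure(c(0, 120), cfg), "other")
  expect_identical(classify_exposure(c(0, 50, 400), cfg), "minimal")  # 350 > 270
  expect_identical(classify_exposure(c(0, 50, 320), cfg), "other")    # inside (50, 320]
  expect_identical(classify_exposure(c(0, 50, 321), cfg), "minimal")  # just outside
  expect_identical(classify_exposure(c(0, 80, 160), cfg), "chronic_pattern")
  # chronic veto dominates any qualifying pair, including equal 50-day gaps
  expect_identical(classify_exposure(c(0, 50, 100), cfg), "chronic_pattern")
  # gaps of exactly 90 escape the chronic veto (< 90), and the trailing
  # pair (90, 180) has a clean tail, so the existential pair rule fires
  expect_identical(classify_exposure(c(0, 90, 180), cfg), "minimal")
  # duplicates collapse: a refill entered twice is not a chronic pattern
  expect_identical(classify_exposure(c(0, 0, 50, 50), cfg), "minimal")
  # all gaps beyond the exclusion window: no qualifying pair
  expect_identical(classify_exposure(c(0, 300, 600), cfg), "other")
  expect_error(classify_exposure(c(-1, 5), cfg), "non-negative")
})

test_that("classifier agrees with the brute-force oracle and partitions inputs", {
  set.seed(7)
  lists <- random_date_lists(1500)
  classes <- c("unexposed", "single_rx", "minimal", "chronic_pattern", "other")
  for (d in lists) {
    got <- classify_exposure(d, cfg)
    expect_identical(got, brute_classify(d))
    expect_true(got %in% classes)
  }
})

test_that("age is an exact year fraction", {
  expect_identical(age_years(0, 0), 0)
  expect_equal(age_years(0, 6574), 17.999, tolerance = 1e-3)
  expect_equal(age_years(0, 18 * 365.25), 18)
  expect_error(age_years(10, 0), "negative age")
})

test_that("cohort membership on the hand-written toy matches hand evaluation", {
  ds <- toy_dataset()
  gen <- build_cohorts(ds, cfg, mode = "generic", require_pool = FALSE)
  exp <- build_cohorts(ds, cfg, mode = "exposed", require_pool = FALSE)
  # cases: OUD code + floor + no cancer -> 1 and 10 (4 fails floor, 5 cancer)
  expect_setequal(gen$case_ids, c(1L, 10L))
  expect_setequal(exp$case_ids, c(1L, 10L))
  # generic controls: no OUD, floor, no cancer, adult -> 2,3,8,11,12
  expect_setequal(gen$eligible_control_ids, c(2L, 3L, 8L, 11L, 12L))
  # exposed adds the minimal-pattern conjunct -> 2,11
  expect_setequal(exp$eligible_control_ids, c(2L, 11L))
  expect_true(all(exp$eligible_control_ids %in% gen$eligible_control_ids))
  # soundness: no control carries an OUD code; disjoint from cases
  expect_length(intersect(gen$case_ids, gen$eligible_control_ids), 0)
  fl <- gen$flags
  expect_false(any(fl$is_case[match(gen$eligible_control_ids, fl$patient_id)]))
  expect_true(all(fl$exposure_class[match(exp$eligible_control_ids, fl$patient_id)] == "minimal"))
})

test_that("exposed mode with no prescriptions errors unless there are no cases", {
  ds <- toy_dataset()
  ds$prescriptions <- ds$prescriptions[0]
  expect_error(build_cohorts(ds, cfg, mode = "exposed"), "shortfall")
  # and the shortfall check names the numbers
  expect_error(build_cohorts(ds, cfg, mode = "exposed"), "eligible control pool")
})

test_that("control exclusion list shrinks the eligible pool", {
  ds <- toy_dataset()
  gen <- build_cohorts(ds, cfg, mode = "generic", exclude_controls = c(2L, 3L),
                       require_pool = FALSE)
  expect_setequal(gen$eligible_control_ids, c(8L, 11L, 12L))
})
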