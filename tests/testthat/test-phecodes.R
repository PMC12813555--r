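write_map_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("phecode map loading handles both dialects and bad input", {
  # long dialect
  f <- write_map_csv(c("code,version,phecode",
                       "Y29620,ICD10,296.20",
                       "V29620,ICD9,296.20",
                       "Y29620,ICD10,296.20"))   # exact duplicate collapses
  m <- load_phecode_map(f)
  expect_equal(nrow(m), 2)
  # published-map dialect: code column named icd9/icd10
  f2 <- write_map_csv(c("icd9,icd10,phecode",
                        "296.2,F32.9,296.20"))
  m2 <- load_phecode_map(f2)
  expect_equal(nrow(m2), 2)
  expect_setequal(m2$version, c("ICD9", "ICD10"))
  expect_identical(m2[version == "ICD9"]$code, "2962")  # dots stripped
  # empty file
  f3 <- write_map_csv("code,version,phecode")
  expect_equal(nrow(load_phecode_map(f3)), 0)
  # conflicting duplicate errors and names the offender
  f4 <- write_map_csv(c("code,version,phecode",
                        "Y111,ICD10,111.00",
                        "Y111,ICD10,222.00"))
  expect_error(load_phecode_map(f4), "Y111")
})

test_that("the packaged toy map and code lists load", {
  f <- system.file("extdata", "toy_phecode_map.csv", package = "oudcontrols")
  m <- load_phecode_map(f)
  expect_gt(nrow(m), 0)
  expect_setequal(unique(m$version), c("ICD9", "ICD10"))
  oud <- read_code_list(system.file("extdata", "oud_codes.txt",
                                    package = "oudcontrols"))
  expect_true("F1120" %in% oud)
  expect_true(is_case("F11.20", oud))
})

test_that("phenotype matrix matches hand enumeration and is idempotent", {
  map <- new_phecode_map(data.table::data.table(
    code = c("Y1", "Y2", "V1"), version = c("ICD10", "ICD10", "ICD9"),
    phecode = c("100.00", "200.00", "100.00")))
  dx <- data.table::data.table(
    patient_id = c(1L, 1L, 2L, 3L, 3L, 4L),
    event_date = 1:6,
    code = c("Y1", "Y2", "Y2", "V1", "ZZZ", "ZZZ"),
    code_version = c("ICD10", "ICD10", "ICD10", "ICD9", "ICD10", "ICD10"))
  m <- suppressMessages(build_phenotype_matrix(dx, map, patient_ids = 1:5))
  expect_identical(dim(m), c(5L, 2L))
  expect_identical(unname(m[, "100.00"]), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(unname(m[, "200.00"]), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # patient 4 has only unmapped codes; patient 5 has none: all-FALSE rows
  expect_false(any(m[4:5, ]))
  # duplicating every event changes nothing
  m2 <- suppressMessages(build_phenotype_matrix(rbind(dx, dx), map, 1:5))
  expect_identical(m, m2)
  # unmapped events reported
  expect_message(build_phenotype_matrix(dx, map, 1:5), "2 unmapped")
})

test_that("parent rollup propagates child phecodes to integer parents", {
  map <- new_phecode_map(data.table::data.table(
    code = c("Y1", "Y2"), version = "ICD10", phecode = c("296.20", "296")))
  dx <- data.table::data.table(patient_id = 1L, event_date = 1L,
                               code = "Y1", code_version = "ICD10")
  m_off <- suppressMessages(build_phenotype_matrix(dx, map, 1L))
  expect_false(m_off[1, "296"])
  m_on <- suppressMessages(build_phenotype_matrix(dx, map, 1L, rollup = TRUE))
  expect_true(m_on[1, "296"])
})

test_that("minimum-case filter counts positives and is monotone", {
  m <- matrix(c(rep(TRUE, 3), rep(FALSE, 7),
                rep(TRUE, 7), rep(FALSE, 3)), ncol = 2,
              dimnames = list(1:10, c("a", "b")))
  expect_identical(colnames(filter_phecodes(m, 0)), c("a", "b"))
  expect_identical(colnames(filter_phecodes(m, 5)), "b")
  expect_equal(ncol(filter_phecodes(m, Inf)), 0)
  for (k in 0:8) {
    expect_true(all(colnames(filter_phecodes(m, k + 1)) %in%
                      colnames(filter_phecodes(m, k))))
  }
})
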