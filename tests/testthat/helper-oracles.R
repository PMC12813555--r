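# Independent brute-force implementation of the exposure-classification
# rules, written as literal nested loops over pairs and consecutive
# triples.  Deliberately kept free of any shared code with
# classify_exposure() so the two can serve as mutual checks.
brute_classify <- function(dates, pair_window = 90, third_excl = 270,
                           chronic_gap = 90) {
  stopifnot(all(dates >= 0))
  d <- sort(unique(dates))
  k <- length(d)
  if (k == 0) return("unexposed")
  if (k == 1) return("single_rx")
  if (k >= 3) {
    for (i in 1:(k - 2)) {
      if ((d[i + 1] - d[i]) < chronic_gap && (d[i + 2] - d[i + 1]) < chronic_gap) {
        return("chronic_pattern")
      }
    }
  }
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      if (d[j] - d[i] <= pair_window) {
        clean <- TRUE
        for (l in 1:k) {
          if (d[l] > d[j] && d[l] <= d[j] + third_excl) clean <- FALSE
        }
        if (clean) return("minimal")
      }
    }
  }
  "other"
}

# random prescription-date lists over a 3000-day span, length <= 8,
# duplicates allowed
random_date_lists <- function(n, max_len = 8, span = 3000) {
  lapply(seq_len(n), function(i) {
    k <- sample(0:max_len, 1)
    if (k == 0) integer(0) else sample(0:span, k, replace = TRUE)
  })
}

# Brute-force sliding-window data floor: try every window anchored at each
# event day, literally.
brute_floor <- function(dates, min_codes = 5, window = 1095) {
  d <- sort(unique(dates))
  if (length(d) < min_codes) return(FALSE)
  for (a in d) {
    if (sum(d >= a & d <= a + window) >= min_codes) return(TRUE)
  }
  FALSE
}

# Hand-written 12-patient toy dataset covering every eligibility
# combination: case status, data floor, cancer, age, exposure class.
# Record span 7300 days; adults born at day -7000 (age ~39), the minor at
# day 2000 (age ~14.5).
toy_dataset <- function() {
  adult <- -7000L
  minor <- 2000L
  floor_days <- c(100L, 200L, 300L, 400L, 500L)  # 5 distinct days, passes
  sparse_days <- c(0L, 2000L, 4000L)             # fails the floor
  p <- data.table::data.table(
    patient_id = 1:12,
    sex = rep(c("F", "M"), 6),
    race = "R1", ethnicity = "E1",
    birth_date = c(rep(adult, 8), minor, rep(adult, 3)),
    site = rep(1:2, 6))
  filler <- function(id, days) data.table::data.table(
    patient_id = id, event_date = days, code = "R99", code_version = "ICD10")
  oud <- function(id, day = 600L) data.table::data.table(
    patient_id = id, event_date = day, code = "F11.20", code_version = "ICD10")
  cancer <- function(id, day = 700L) data.table::data.table(
    patient_id = id, event_date = day, code = "C50.9", code_version = "ICD10")
  dx <- data.table::rbindlist(list(
    filler(1L, floor_days), oud(1L),                  # case, floor ok
    filler(2L, floor_days),                           # generic-eligible, minimal rx
    filler(3L, floor_days),                           # generic-eligible, unexposed
    filler(4L, sparse_days), oud(4L),                 # case but fails floor
    filler(5L, floor_days), oud(5L), cancer(5L),      # case excluded by cancer
    filler(6L, floor_days), cancer(6L),               # control excluded by cancer
    filler(7L, sparse_days),                          # control fails floor
    filler(8L, floor_days),                           # generic-eligible, chronic rx
    filler(9L, floor_days + 2000L),                   # minor: age-excluded control
    filler(10L, floor_days), oud(10L),                # case, floor ok
    filler(11L, floor_days),                          # generic-eligible, minimal rx
    filler(12L, floor_days)                           # generic-eligible, single rx
  ))
  rx <- data.table::rbindlist(list(
    data.table::data.table(patient_id = 2L, event_date = c(1000L, 1050L), opioid = TRUE),
    data.table::data.table(patient_id = 8L, event_date = c(1000L, 1050L, 1100L), opioid = TRUE),
    data.table::data.table(patient_id = 9L, event_date = c(3000L, 3050L), opioid = TRUE),
    data.table::data.table(patient_id = 11L, event_date = c(2000L, 2080L), opioid = TRUE),
    data.table::data.table(patient_id = 12L, event_date = 1500L, opioid = TRUE),
    data.table::data.table(patient_id = 3L, event_date = 1500L, opioid = FALSE)
  ))
  new_ehr_dataset(p, dx, rx, 7300L)
}

# simulated summary-statistic pair with known multiplicative dilution
sim_sumstats_pair <- function(m = 5000, delta = 1.25, beta_sd = 0.02,
                              se_ref = 0.01, se_study = 0.01) {
  b <- stats::rnorm(m, 0, beta_sd)
  alle <- t(vapply(seq_len(m), function(j) sample(c("A", "C"), 2), character(2)))
  mk <- function(beta, se) data.table::data.table(
    variant_id = sprintf("rs%05d", seq_len(m)),
    effect_allele = alle[, 1], other_allele = alle[, 2],
    beta = beta, se = se, p = 0.5, maf = 0.2, n = 10000L)
  list(ref = mk(b + stats::rnorm(m, 0, se_ref), se_ref),
       study = mk(b / delta + stats::rnorm(m, 0, se_study), se_study))
}
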