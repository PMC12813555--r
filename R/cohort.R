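#' Does a patient carry an OUD case code?
#'
#' A patient is an OUD case if at least one of their diagnosis codes is in
#' the OUD code set.  Codes are compared after [normalize_icd()]; the test
#' is idempotent in code multiplicity.
#'
#' @param codes character vector of the patient's diagnosis codes (may be
#'   empty).
#' @param oud_codes normalized OUD code set.
#' @return logical scalar.
#' @export
is_case <- function(codes, oud_codes) {
  any(normalize_icd(codes) %in% oud_codes)
}

#' Does a patient carry a cancer code?
#'
#' Cancer diagnoses trigger exclusion from both cases and controls because
#' long-term analgesia for cancer pain confounds opioid-exposure patterns.
#'
#' @inheritParams is_case
#' @param cancer_codes normalized cancer code set.
#' @return logical scalar.
#' @export
has_cancer <- function(codes, cancer_codes) {
  any(normalize_icd(codes) %in% cancer_codes)
}

#' Medical-home data floor
#'
#' TRUE iff some window of `floor_window_days` days (inclusive of both
#' endpoints) contains at least `floor_min_codes` distinct diagnosis days.
#' Windows are anchored at each event day — the sliding-window reading of
#' "five ICD codes on different days over a 3-year period".  Duplicate
#' same-day events count once.  Adding an event can never flip the result
#' from TRUE to FALSE.
#'
#' @param dates integer day offsets of the patient's diagnosis events.
#' @param config a [cohort_config()].
#' @return logical scalar.
#' @export
meets_data_floor <- function(dates, config) {
  d <- sort(unique(as.numeric(dates)))
  k <- config$floor_min_codes
  n <- length(d)
  if (n < k) return(FALSE)
  # window [d_i, d_i + W] holds >= k distinct days iff d_{i+k-1} - d_i <= W
  any(d[k:n] - d[1:(n - k + 1L)] <= config$floor_window_days)
}

#' Classify a patient's opioid-prescription pattern
#'
#' Classifies the distinct prescription days d1 < ... < dk into one of five
#' exclusive classes:
#'
#' * `unexposed` — no prescriptions (k = 0);
#' * `single_rx` — exactly one prescription day;
#' * `chronic_pattern` — some three consecutive prescription days have both
#'   gaps strictly below `chronic_gap_days`; this veto dominates every
#'   other rule, flagging use patterns consistent with chronic therapy;
#' * `minimal` — no chronic pattern, and some pair (di, dj) with
#'   dj - di <= `pair_window_days` has no other prescription inside the
#'   half-open window (dj, dj + `third_rx_exclusion_days`]; this is the
#'   "at least two prescriptions no more than 90 days apart, no third one
#'   within 9 months of the second" rule, and the only class eligible for
#'   the exposed control group;
#' * `other` — two or more prescription days with neither pattern.
#'
#' The qualifying pair is existential: any pair with a clean 9-month tail
#' qualifies, with the chronic veto guarding against over-inclusion.
#' Same-day duplicate prescriptions collapse to one event so that refills
#' entered twice cannot fabricate a chronic pattern.
#'
#' @param dates integer day offsets of opioid prescriptions; duplicates
#'   allowed; negative dates are rejected.
#' @param config a [cohort_config()].
#' @return one of `"unexposed"`, `"single_rx"`, `"minimal"`,
#'   `"chronic_pattern"`, `"other"`.
#' @export
classify_exposure <- function(dates, config) {
  d <- as.numeric(dates)
  abort_if(any(d < 0), "prescription dates must be non-negative day offsets")
  d <- sort(unique(d))
  k <- length(d)
  if (k == 0L) return("unexposed")
  if (k == 1L) return("single_rx")
  gaps <- diff(d)
  if (k >= 3L) {
    g1 <- gaps[-length(gaps)]
    g2 <- gaps[-1L]
    if (any(g1 < config$chronic_gap_days & g2 < config$chronic_gap_days)) {
      return("chronic_pattern")
    }
  }
  # existential pair search: dj - di <= pair window, clean tail after dj
  for (j in 2:k) {
    if (any(d[j] - d[1:(j - 1L)] <= config$pair_window_days)) {
      tail_lo <- d[j]
      tail_hi <- d[j] + config$third_rx_exclusion_days
      if (!any(d > tail_lo & d <= tail_hi)) return("minimal")
    }
  }
  "other"
}

#' Exact age in years
#'
#' Year-fraction age using the mean Julian year of 365.25 days.
#'
#' @param birth_date,reference_date integer day offsets from the dataset
#'   epoch; reference is normally the dataset end date.
#' @return numeric age in years.
#' @export
age_years <- function(birth_date, reference_date) {
  age <- (as.numeric(reference_date) - as.numeric(birth_date)) / 365.25
  abort_if(any(age < 0), "negative age: birth date after reference date")
  age
}

#' Build case and eligible-control sets from an EHR dataset
#'
#' Implements the phenotyping flowchart.  Cases carry at least one OUD
#' code, pass the data floor and have no cancer code.  Eligible controls
#' carry no OUD code, pass the floor, have no cancer code and are at least
#' `min_control_age_years` old at the dataset end date; in `mode =
#' "exposed"` controls are further restricted to the `minimal`
#' prescription-pattern class.  The age rule is applied to controls only,
#' as in the source design.
#'
#' @param dataset an `ehr_dataset` (see [generate_dataset()] or
#'   [read_ehr_dataset()]).
#' @param config a [cohort_config()].
#' @param mode `"generic"` or `"exposed"`.
#' @param exclude_controls patient ids removed from the eligible-control
#'   pool before the shortfall check — used to keep the generic and
#'   exposed control groups disjoint when both are drawn from one dataset.
#' @param require_pool if TRUE (default) error when the eligible pool is
#'   smaller than `match_ratio` times the case count.
#' @return an object of class `cohort`: list with `case_ids`,
#'   `eligible_control_ids`, `mode`, and a per-patient `flags` data.table
#'   (patient_id, is_case, floor, cancer, age, exposure_class, eligibility
#'   flags).
#' @export
build_cohorts <- function(dataset, config, mode = c("generic", "exposed"),
                          exclude_controls = NULL, require_pool = TRUE) {
  mode <- match.arg(mode)
  flags <- patient_flags(dataset, config)

  case_sel <- flags$is_case & flags$floor & !flags$cancer
  ctrl_sel <- !flags$is_case & flags$floor & !flags$cancer &
    flags$age >= config$min_control_age_years
  if (mode == "exposed") {
    ctrl_sel <- ctrl_sel & flags$exposure_class == "minimal"
  }
  flags$eligible_case <- case_sel
  flags$eligible_control <- ctrl_sel

  case_ids <- flags$patient_id[case_sel]
  ctrl_ids <- flags$patient_id[ctrl_sel]
  if (!is.null(exclude_controls)) {
    ctrl_ids <- setdiff(ctrl_ids, exclude_controls)
  }
  need <- config$match_ratio * length(case_ids)
  if (require_pool && length(ctrl_ids) < need) {
    stop(sprintf(
      "mode '%s': eligible control pool (%d) smaller than match_ratio x cases (%d); shortfall %d",
      mode, length(ctrl_ids), need, need - length(ctrl_ids)), call. = FALSE)
  }
  structure(list(case_ids = case_ids, eligible_control_ids = ctrl_ids,
                 mode = mode, flags = flags),
            class = "cohort")
}

# Per-patient eligibility flags for every rule; shared by both modes.
patient_flags <- function(dataset, config) {
  pid <- dataset$patients$patient_id
  dx <- dataset$diagnoses
  rx <- dataset$prescriptions

  code_norm <- normalize_icd(dx$code)
  oud_by_pat <- tapply(code_norm %in% config$oud_codes, dx$patient_id, any)
  cancer_by_pat <- tapply(code_norm %in% config$cancer_codes, dx$patient_id, any)

  floor_by_pat <- vapply(split(dx$event_date, dx$patient_id),
                         meets_data_floor, logical(1), config = config)

  opi <- rx[rx$opioid == TRUE, , drop = FALSE]
  expo_by_pat <- vapply(split(opi$event_date, opi$patient_id),
                        classify_exposure, character(1), config = config)

  idx <- function(v, default) {
    out <- v[match(as.character(pid), names(v))]
    out[is.na(out)] <- default
    unname(out)
  }
  data.table::data.table(
    patient_id = pid,
    site = dataset$patients$site,
    is_case = idx(oud_by_pat, FALSE),
    cancer = idx(cancer_by_pat, FALSE),
    floor = idx(floor_by_pat, FALSE),
    age = age_years(dataset$patients$birth_date, dataset$dataset_end_date),
    exposure_class = idx(expo_by_pat, "unexposed")
  )
}
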