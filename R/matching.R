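#' Median age of record
#'
#' The median of the patient's age at each distinct diagnosis day — the
#' demographic matching variable summarising when in life the record was
#' accrued.  Uses the standard midpoint convention for even counts.
#'
#' @param diagnosis_dates integer day offsets of the patient's diagnosis
#'   events.
#' @param birth_date integer day offset of birth.
#' @return numeric age in years; `NA` when there are no events.
#' @export
median_age_of_record <- function(diagnosis_dates, birth_date) {
  d <- unique(as.numeric(diagnosis_dates))
  if (length(d) == 0L) return(NA_real_)
  stats::median(age_years(birth_date, d))
}

#' Ratio-match controls to cases within exact demographic strata
#'
#' Greedy nearest-neighbour matching without replacement: within each
#' exact stratum (identical values of all `exact_vars`), each case — in an
#' order randomized by `seed` — takes the `ratio` still-unused controls
#' nearest in `nearest_var`, with ties broken by smaller patient id.  A
#' case whose stratum holds fewer controls keeps what exists and is
#' flagged as under-matched; an optional caliper drops candidate controls
#' whose `nearest_var` distance exceeds it.  Deterministic given the seed.
#'
#' @param cases data.frame of cases with `patient_id`, the `exact_vars`
#'   and `nearest_var` columns.
#' @param controls data.frame of eligible controls, same columns; must be
#'   disjoint from the cases.
#' @param ratio controls per case.
#' @param exact_vars character vector of exact-match column names.
#' @param nearest_var column matched by nearest neighbour (median age of
#'   record).
#' @param caliper maximum allowed `nearest_var` distance (`Inf` = none).
#' @param seed integer seed for the case-order randomization.
#' @return a `matched_cohort`: list with `assignment` (data.table: set_id,
#'   case_id, control_id), `case_ids`, `control_ids`, `achieved_ratio`
#'   (named per case), `under_matched` (case ids), plus the matching
#'   variables used.
#' @export
match_controls <- function(cases, controls, ratio = 4L,
                           exact_vars = c("race", "ethnicity", "sex"),
                           nearest_var = "median_age",
                           caliper = Inf, seed = 1L) {
  cases <- data.table::as.data.table(cases)
  controls <- data.table::as.data.table(controls)
  abort_if(nrow(controls) == 0L, "empty control pool")
  abort_if(length(intersect(cases$patient_id, controls$patient_id)) > 0,
           "control pool overlaps the case set")
  need <- c("patient_id", exact_vars, nearest_var)
  for (df in list(cases, controls)) {
    abort_if(!all(need %in% names(df)), "matching tables need columns: %s",
             paste(need, collapse = ", "))
  }
  stratum_key <- function(df) {
    do.call(paste, c(df[, exact_vars, with = FALSE], list(sep = "\r")))
  }
  cases <- cases[order(patient_id)]
  controls <- controls[order(patient_id)]
  cs <- stratum_key(cases)
  ks <- stratum_key(controls)

  case_order <- with_seed(seed, sample.int(nrow(cases)))
  assign_list <- vector("list", nrow(cases))
  used <- rep(FALSE, nrow(controls))
  cage <- cases[[nearest_var]]
  kage <- controls[[nearest_var]]
  strat_idx <- split(seq_len(nrow(controls)), ks)

  for (ci in case_order) {
    cand <- strat_idx[[cs[ci]]]
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) next
    dist <- abs(kage[cand] - cage[ci])
    keep <- dist <= caliper
    cand <- cand[keep]
    dist <- dist[keep]
    if (length(cand) == 0L) next
    # nearest first; ties by smaller patient id (controls sorted by id)
    take <- cand[order(dist, cand)][seq_len(min(ratio, length(cand)))]
    used[take] <- TRUE
    assign_list[[ci]] <- data.table::data.table(
      case_id = cases$patient_id[ci],
      control_id = controls$patient_id[take])
  }
  assignment <- data.table::rbindlist(assign_list[!vapply(assign_list, is.null, logical(1))])
  if (nrow(assignment) == 0L) {
    assignment <- data.table::data.table(case_id = integer(0), control_id = integer(0))
  }
  data.table::setorder(assignment, case_id, control_id)
  assignment[, set_id := match(case_id, unique(case_id))]
  data.table::setcolorder(assignment, c("set_id", "case_id", "control_id"))
  ach <- assignment[, .N, by = case_id]
  achieved <- stats::setNames(rep(0L, nrow(cases)), cases$patient_id)
  achieved[as.character(ach$case_id)] <- ach$N
  structure(list(
    assignment = assignment[],
    case_ids = cases$patient_id,
    control_ids = assignment$control_id,
    achieved_ratio = achieved,
    under_matched = cases$patient_id[achieved < ratio],
    exact_vars = exact_vars, nearest_var = nearest_var,
    ratio = as.integer(ratio), caliper = caliper, seed = as.integer(seed)
  ), class = "matched_cohort")
}
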