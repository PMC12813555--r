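#' Cohort-definition configuration
#'
#' Collects every threshold used by the phenotyping algorithms: the
#' prescription-pair window, the third-prescription exclusion window, the
#' chronic-use gap, the medical-home data floor, the control age minimum,
#' the matching ratio, the minimum phecode case count, the significance
#' level and the minor-allele-frequency floor.
#'
#' The defaults encode the study design this package reproduces: two opioid
#' prescriptions no more than 90 days apart with no third prescription
#' within 9 months (270 days) of the second define minimal exposure; three
#' prescriptions with consecutive gaps under 90 days define a chronic-use
#' pattern; the data floor requires at least five ICD codes on distinct
#' days within a 3-year (1095-day) window; controls must be at least 18
#' years old; controls are matched 4:1 to cases; phecodes need at least 100
#' positive patients; variants below MAF 0.05 are dropped.
#'
#' @param oud_codes character vector of ICD codes defining OUD case status
#'   (compared after [normalize_icd()]).
#' @param cancer_codes character vector of ICD codes triggering the cancer
#'   exclusion.
#' @param pair_window_days maximum gap, in days, between the two
#'   prescriptions of a qualifying minimal-exposure pair (gap \eqn{\le}
#'   window qualifies).
#' @param third_rx_exclusion_days length of the window after the second
#'   prescription of a pair in which any further prescription disqualifies
#'   the pair; the window is the half-open interval (d2, d2 + 270].
#' @param chronic_gap_days three prescriptions whose consecutive gaps are
#'   both strictly below this value mark a chronic-use pattern.
#' @param floor_min_codes minimum number of distinct diagnosis days
#'   required inside one floor window.
#' @param floor_window_days length of the sliding data-floor window,
#'   inclusive of both endpoints.
#' @param min_control_age_years minimum control age at the dataset end date.
#' @param match_ratio controls matched per case.
#' @param min_phecode_cases minimum number of phecode-positive patients for
#'   a phecode to be analysed.
#' @param alpha family-wise significance level before Bonferroni division.
#' @param maf_min minor-allele-frequency floor for the variant scan.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(oud_codes = c("F1120", "F1110", "F1190", "30400", "30470", "30550"),
                          cancer_codes = c("C509", "C61", "C349", "1749", "185", "1629"),
                          pair_window_days = 90L,
                          third_rx_exclusion_days = 270L,
                          chronic_gap_days = 90L,
                          floor_min_codes = 5L,
                          floor_window_days = 1095L,
                          min_control_age_years = 18,
                          match_ratio = 4L,
                          min_phecode_cases = 100L,
                          alpha = 0.05,
                          maf_min = 0.05) {
  abort_if(!is_count(pair_window_days, 1L), "pair_window_days must be a positive count")
  abort_if(!is_count(third_rx_exclusion_days, 1L), "third_rx_exclusion_days must be a positive count")
  abort_if(!is_count(chronic_gap_days, 1L), "chronic_gap_days must be a positive count")
  abort_if(!is_count(floor_min_codes, 1L), "floor_min_codes must be a positive count")
  abort_if(!is_count(floor_window_days, 1L), "floor_window_days must be a positive count")
  abort_if(!is_count(match_ratio, 1L), "match_ratio must be >= 1")
  abort_if(!is_count(min_phecode_cases, 0L), "min_phecode_cases must be a count")
  abort_if(!(is_prob(alpha) && alpha > 0 && alpha < 1), "alpha must be in (0,1)")
  abort_if(!(is_prob(maf_min) && maf_min < 0.5), "maf_min must be in [0, 0.5)")
  abort_if(!is.numeric(min_control_age_years) || min_control_age_years < 0,
           "min_control_age_years must be non-negative")
  structure(list(
    oud_codes = normalize_icd(oud_codes),
    cancer_codes = normalize_icd(cancer_codes),
    pair_window_days = as.integer(pair_window_days),
    third_rx_exclusion_days = as.integer(third_rx_exclusion_days),
    chronic_gap_days = as.integer(chronic_gap_days),
    floor_min_codes = as.integer(floor_min_codes),
    floor_window_days = as.integer(floor_window_days),
    min_control_age_years = as.numeric(min_control_age_years),
    match_ratio = as.integer(match_ratio),
    min_phecode_cases = as.integer(min_phecode_cases),
    alpha = as.numeric(alpha),
    maf_min = as.numeric(maf_min)
  ), class = "cohort_config")
}

#' Specify a simulated comorbidity phecode
#'
#' Each comorbidity is a phecode whose per-patient probability follows a
#' logistic model: `logit(p) = logit(prevalence) + log_or_case * case +
#' log_or_exposure * propensity + site_shift[site]`.  The exposure
#' propensity is the latent standard-normal score that also drives the
#' prescription-pattern class, so a positive `log_or_exposure` makes the
#' phecode more common among opioid-exposed patients — the structure that
#' produces effect-size attenuation against exposed controls.
#'
#' @param phecode dotted-string phecode label, e.g. `"296.20"`.
#' @param prevalence baseline prevalence in (0, 1).
#' @param log_or_case log odds ratio versus case status.
#' @param log_or_exposure log odds ratio per SD of exposure propensity.
#' @param site_shift numeric vector of per-site log-odds shifts (recycled
#'   across sites; default 0).
#' @return a `comorbidity_spec` list.
#' @export
comorbidity_spec <- function(phecode, prevalence, log_or_case = 0,
                             log_or_exposure = 0, site_shift = 0) {
  abort_if(!is.character(phecode) || length(phecode) != 1L,
           "phecode must be a single string")
  abort_if(!(is.numeric(prevalence) && length(prevalence) == 1L &&
               prevalence > 0 && prevalence < 1),
           "comorbidity '%s': prevalence must lie strictly inside (0,1)", phecode)
  abort_if(!is.finite(log_or_case) || !is.finite(log_or_exposure),
           "comorbidity '%s': log odds ratios must be finite", phecode)
  structure(list(phecode = phecode, prevalence = prevalence,
                 log_or_case = log_or_case, log_or_exposure = log_or_exposure,
                 site_shift = site_shift),
            class = "comorbidity_spec")
}

#' Synthetic-EHR generator configuration
#'
#' Defines the generative model for the synthetic longitudinal EHR: number
#' of patients and sites, OUD case prevalence, the distribution of
#' prescription-pattern classes within cases and non-cases, the target
#' share of non-cases with at least one opioid prescription, the
#' comorbidity phecodes, the record span, the share of patients built to
#' fail the data floor, and the genotype/liability model.
#'
#' The default non-case prescription prevalence of 0.8273 reflects the high
#' background opioid-prescription exposure observed in tertiary-care
#' hospital populations.  When `prescription_prevalence_noncase` is given,
#' the non-case probability of the `none` class is set to one minus it and
#' the remaining class probabilities are rescaled proportionally, so the
#' realized share of non-cases with any opioid prescription tracks the knob.
#'
#' @param n_patients number of patients.
#' @param n_sites number of sites (default 2).
#' @param case_prevalence target OUD case prevalence.
#' @param exposure_class_probs named list with elements `case` and
#'   `noncase`, each a named probability vector over
#'   `c("none","single","minimal","chronic")` summing to 1.
#' @param prescription_prevalence_noncase target share of non-cases with at
#'   least one opioid prescription; `NULL` leaves `exposure_class_probs`
#'   untouched.
#' @param comorbidity_specs list of [comorbidity_spec()] objects.
#' @param record_span_days length of the observation window in days; day 0
#'   is the dataset epoch and `record_span_days` the dataset end date.
#' @param floor_failure_rate share of patients generated to fail the
#'   medical-home data floor.
#' @param age_range_years range of patient age (years) at the dataset end
#'   date; ages are drawn uniformly, so a lower bound under 18 exercises
#'   the control age exclusion.
#' @param n_variants,maf_range,n_causal,heritability_liability genotype and
#'   liability-threshold model: biallelic variant count, allele-frequency
#'   interval within (0, 0.5], causal variant count, and liability-scale
#'   heritability in [0, 1].
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the config and seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_patients = 20000L,
                             n_sites = 2L,
                             case_prevalence = 0.06,
                             exposure_class_probs = list(
                               case    = c(none = 0.05, single = 0.15, minimal = 0.30, chronic = 0.50),
                               noncase = c(none = 0.1727, single = 0.30, minimal = 0.37, chronic = 0.1573)
                             ),
                             prescription_prevalence_noncase = 0.8273,
                             comorbidity_specs = default_comorbidities(),
                             record_span_days = 7300L,
                             floor_failure_rate = 0.10,
                             age_range_years = c(12, 90),
                             n_variants = 500L,
                             maf_range = c(0.05, 0.5),
                             n_causal = min(20L, n_variants),
                             heritability_liability = 0.3,
                             seed = 1L) {
  abort_if(!is_count(n_patients, 1L), "n_patients must be a positive count")
  abort_if(!is_count(n_sites, 1L), "n_sites must be a positive count")
  abort_if(!is_prob(case_prevalence), "case_prevalence must be a probability")
  abort_if(!is_prob(floor_failure_rate), "floor_failure_rate must be a probability")
  abort_if(!is_count(record_span_days, 730L),
           "record_span_days must be at least 730 (two years)")
  abort_if(!is_count(n_variants, 0L), "n_variants must be a count")
  abort_if(!(is.numeric(maf_range) && length(maf_range) == 2L &&
               maf_range[1] > 0 && maf_range[2] <= 0.5 &&
               maf_range[1] <= maf_range[2]),
           "maf_range must be an interval within (0, 0.5]")
  abort_if(!is_count(n_causal, 0L) || n_causal > n_variants,
           "n_causal must be a count <= n_variants")
  abort_if(!is_prob(heritability_liability),
           "heritability_liability must lie in [0,1]")
  abort_if(!(is.numeric(age_range_years) && length(age_range_years) == 2L &&
               age_range_years[1] >= 3 && age_range_years[1] <= age_range_years[2]),
           "age_range_years must be an interval with lower bound >= 3 (every record span must fit the floor window and a two-year prescription pattern)")

  classes <- c("none", "single", "minimal", "chronic")
  abort_if(!setequal(names(exposure_class_probs), c("case", "noncase")),
           "exposure_class_probs needs elements 'case' and 'noncase'")
  for (s in c("case", "noncase")) {
    p <- exposure_class_probs[[s]]
    abort_if(!setequal(names(p), classes),
             "exposure_class_probs$%s must name classes none/single/minimal/chronic", s)
    p <- p[classes]
    abort_if(any(p < 0) || abs(sum(p) - 1) > 1e-8,
             "exposure_class_probs$%s must be non-negative and sum to 1", s)
    exposure_class_probs[[s]] <- p
  }
  if (!is.null(prescription_prevalence_noncase)) {
    abort_if(!is_prob(prescription_prevalence_noncase),
             "prescription_prevalence_noncase must be a probability")
    p <- exposure_class_probs$noncase
    rest <- p[c("single", "minimal", "chronic")]
    abort_if(sum(rest) <= 0 && prescription_prevalence_noncase > 0,
             "cannot target a positive prescription prevalence with zero mass on exposed classes")
    p["none"] <- 1 - prescription_prevalence_noncase
    if (sum(rest) > 0) {
      p[c("single", "minimal", "chronic")] <-
        rest / sum(rest) * prescription_prevalence_noncase
    }
    exposure_class_probs$noncase <- p
  }
  for (cs in comorbidity_specs) {
    abort_if(!inherits(cs, "comorbidity_spec"),
             "comorbidity_specs must be a list of comorbidity_spec objects")
  }
  phe <- vapply(comorbidity_specs, `[[`, "", "phecode")
  abort_if(anyDuplicated(phe) > 0, "duplicate comorbidity phecode '%s'",
           phe[duplicated(phe)][1])

  structure(list(
    n_patients = as.integer(n_patients),
    n_sites = as.integer(n_sites),
    case_prevalence = case_prevalence,
    exposure_class_probs = exposure_class_probs,
    prescription_prevalence_noncase = prescription_prevalence_noncase,
    comorbidity_specs = comorbidity_specs,
    record_span_days = as.integer(record_span_days),
    floor_failure_rate = floor_failure_rate,
    age_range_years = as.numeric(age_range_years),
    n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    n_causal = as.integer(n_causal),
    heritability_liability = heritability_liability,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default comorbidity panel for the synthetic generator
#'
#' A small panel mixing phecodes associated with case status only, with
#' exposure propensity only, with both (the configuration that produces
#' effect-size attenuation against exposed controls), and null phecodes.
#'
#' @param n_null number of additional null phecodes (no case or exposure
#'   effect) appended to the panel.
#' @return list of [comorbidity_spec()] objects.
#' @export
default_comorbidities <- function(n_null = 10L) {
  base <- list(
    comorbidity_spec("296.20", 0.10, log_or_case = log(4),  log_or_exposure = 0.5),
    comorbidity_spec("295.10", 0.03, log_or_case = log(10), log_or_exposure = 0.4),
    comorbidity_spec("318.00", 0.08, log_or_case = log(6),  log_or_exposure = 0.6),
    comorbidity_spec("327.40", 0.12, log_or_case = log(3),  log_or_exposure = 0.7),
    comorbidity_spec("338.20", 0.20, log_or_case = log(2.5), log_or_exposure = 0.9),
    comorbidity_spec("401.10", 0.25, log_or_case = log(1.5), log_or_exposure = 0.3),
    comorbidity_spec("540.10", 0.05, log_or_case = log(2),  log_or_exposure = 0.5),
    comorbidity_spec("760.00", 0.15, log_or_case = log(2.2), log_or_exposure = 0.8,
                     site_shift = c(0, 0.2)),
    comorbidity_spec("300.10", 0.10, log_or_case = 0, log_or_exposure = 0.6),
    comorbidity_spec("495.00", 0.12, log_or_case = 0, log_or_exposure = 0)
  )
  nulls <- lapply(seq_len(n_null), function(i) {
    comorbidity_spec(sprintf("900.%02d", i), 0.10)
  })
  c(base, nulls)
}
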