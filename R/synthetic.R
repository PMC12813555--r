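#' Realize a prescription-date pattern for one patient
#'
#' Emits opioid-prescription day offsets that classify, via
#' [classify_exposure()], exactly as the requested class — the round-trip
#' contract of the generator:
#'
#' * `none` — empty vector;
#' * `single` — one uniform day in the span;
#' * `minimal` — exactly two days, gap drawn uniformly from 1..90 days;
#' * `chronic` — three days whose consecutive gaps are drawn uniformly
#'   from 1..89 days (both strictly below the 90-day chronic threshold).
#'
#' Uses the current RNG state.
#'
#' @param class one of `"none"`, `"single"`, `"minimal"`, `"chronic"`.
#' @param span integer vector `c(first, last)` day of the patient's record;
#'   must cover at least two years for `minimal` and `chronic`.
#' @return integer vector of day offsets (possibly empty).
#' @export
realize_exposure_pattern <- function(class = c("none", "single", "minimal", "chronic"),
                                     span) {
  class <- match.arg(class)
  abort_if(!(is.numeric(span) && length(span) == 2L && span[2] >= span[1]),
           "span must be c(first, last) with last >= first")
  lo <- as.integer(span[1]); hi <- as.integer(span[2])
  if (class %in% c("minimal", "chronic")) {
    abort_if(hi - lo < 730L, "span must cover at least two years for class '%s'", class)
  }
  switch(class,
    none = integer(0),
    single = lo + sample.int(hi - lo + 1L, 1L) - 1L,
    minimal = {
      g <- sample.int(90L, 1L)
      s <- lo + sample.int(hi - lo - g + 1L, 1L) - 1L
      c(s, s + g)
    },
    chronic = {
      g <- sample.int(89L, 2L, replace = TRUE)
      s <- lo + sample.int(hi - lo - sum(g) + 1L, 1L) - 1L
      cumsum(c(s, g))
    }
  )
}

# vectorized pattern realization; returns data.table(patient_id, event_date)
realize_patterns_bulk <- function(class, lo, hi) {
  n <- length(class)
  out <- vector("list", 4L)
  i_single <- which(class == "single")
  if (length(i_single)) {
    d <- lo[i_single] + floor(stats::runif(length(i_single)) * (hi[i_single] - lo[i_single] + 1))
    out[[1L]] <- data.table::data.table(patient_id = i_single, event_date = as.integer(d))
  }
  i_min <- which(class == "minimal")
  if (length(i_min)) {
    g <- sample.int(90L, length(i_min), replace = TRUE)
    s <- lo[i_min] + floor(stats::runif(length(i_min)) * (hi[i_min] - lo[i_min] - g + 1))
    out[[2L]] <- data.table::data.table(
      patient_id = rep(i_min, 2L),
      event_date = as.integer(c(s, s + g)))
  }
  i_chr <- which(class == "chronic")
  if (length(i_chr)) {
    g1 <- sample.int(89L, length(i_chr), replace = TRUE)
    g2 <- sample.int(89L, length(i_chr), replace = TRUE)
    s <- lo[i_chr] + floor(stats::runif(length(i_chr)) * (hi[i_chr] - lo[i_chr] - g1 - g2 + 1))
    out[[3L]] <- data.table::data.table(
      patient_id = rep(i_chr, 3L),
      event_date = as.integer(c(s, s + g1, s + g1 + g2)))
  }
  data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
}

#' Simulate independent biallelic genotypes
#'
#' Dosages are drawn `Binomial(2, f_j)` per variant with allele frequency
#' `f_j` uniform over `maf_range`; variants are independent (no linkage
#' disequilibrium).  Allele labels are sampled without replacement from
#' A/C/G/T.  Uses the current RNG state.
#'
#' @param n number of individuals (>= 1).
#' @param m number of variants (>= 1).
#' @param maf_range allele-frequency interval within (0, 0.5].
#' @return a `genotype_matrix`: list with integer `dosages` (n x m),
#'   `variant_id`, `effect_allele`, `other_allele`, `maf` (generating
#'   frequency) and `obs_freq` (realized allele frequency).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5)) {
  abort_if(!is_count(n, 1L), "n must be >= 1")
  abort_if(!is_count(m, 1L), "m must be >= 1")
  abort_if(!(is.numeric(maf_range) && length(maf_range) == 2L &&
               maf_range[1] > 0 && maf_range[2] <= 0.5 &&
               maf_range[1] <= maf_range[2]),
           "maf_range must be a non-empty interval within (0, 0.5]")
  f <- stats::runif(m, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n * m, 2L, rep(f, each = n)), nrow = n, ncol = m)
  alle <- t(vapply(seq_len(m), function(j) sample(c("A", "C", "G", "T"), 2L),
                   character(2)))
  vid <- sprintf("rs%06d", seq_len(m))
  colnames(dos) <- vid
  structure(list(
    dosages = dos, variant_id = vid,
    effect_allele = alle[, 1L], other_allele = alle[, 2L],
    maf = f, obs_freq = colMeans(dos) / 2
  ), class = "genotype_matrix")
}

#' Liability-threshold phenotype on simulated genotypes
#'
#' The latent liability is a standardized genetic score over `n_causal`
#' variants with equal effect weights, scaled to explain
#' `heritability_liability` of the liability variance, plus independent
#' normal noise.  Case status is liability above the empirical
#' `1 - case_prevalence` quantile, so the realized prevalence matches the
#' target up to discreteness.  Uses the current RNG state.
#'
#' @param genotypes a `genotype_matrix`.
#' @param case_prevalence target case share in [0, 1].
#' @param n_causal number of causal variants (first `n_causal` columns).
#' @param heritability_liability liability-scale heritability in [0, 1].
#' @return list with logical `case`, numeric `liability` (mean 0, sd 1) and
#'   integer vector `causal_idx`.
#' @export
simulate_liability_phenotype <- function(genotypes, case_prevalence,
                                         n_causal, heritability_liability) {
  abort_if(!is_prob(heritability_liability), "heritability must lie in [0,1]")
  abort_if(!is_prob(case_prevalence), "case_prevalence must lie in [0,1]")
  m <- ncol(genotypes$dosages)
  abort_if(!is_count(n_causal, 0L) || n_causal > m, "n_causal must be <= number of variants")
  n <- nrow(genotypes$dosages)
  h2 <- heritability_liability
  causal <- seq_len(n_causal)
  if (n_causal > 0L && h2 > 0) {
    G <- genotypes$dosages[, causal, drop = FALSE]
    f <- genotypes$maf[causal]
    Gs <- sweep(sweep(G, 2L, 2 * f), 2L, sqrt(2 * f * (1 - f)), "/")
    score <- rowSums(Gs) / sqrt(n_causal)
    liab <- sqrt(h2) * score + sqrt(1 - h2) * stats::rnorm(n)
  } else {
    liab <- stats::rnorm(n)
  }
  liab <- as.numeric(scale(liab))
  case <- if (case_prevalence <= 0) {
    rep(FALSE, n)
  } else if (case_prevalence >= 1) {
    rep(TRUE, n)
  } else {
    liab > stats::quantile(liab, 1 - case_prevalence, names = FALSE)
  }
  list(case = case, liability = liab, causal_idx = causal)
}

#' Toy phecode map for a comorbidity panel
#'
#' Builds a small two-dialect map: every comorbidity phecode receives one
#' synthetic ICD-9-style code (`V` prefix) and one ICD-10-style code (`Y`
#' prefix).  The codes are synthetic placeholders, not real ICD entries.
#'
#' @param specs list of [comorbidity_spec()] objects.
#' @return data.table with columns `code`, `version`, `phecode`.
#' @export
toy_phecode_map <- function(specs) {
  phe <- vapply(specs, `[[`, "", "phecode")
  stripped <- gsub("\\.", "", phe)
  data.table::data.table(
    code = c(paste0("V", stripped), paste0("Y", stripped)),
    version = rep(c("ICD9", "ICD10"), each = length(phe)),
    phecode = rep(phe, 2L)
  )
}

#' Generate a synthetic longitudinal EHR dataset with genotypes and truth
#'
#' Produces per-site patient, diagnosis and prescription tables whose
#' statistical structure matches the assumptions of the downstream
#' analyses: OUD case status arises from a liability-threshold model over
#' simulated genotypes; a latent standard-normal exposure propensity
#' drives both the opioid-prescription pattern class (via per-stratum
#' quantile thresholds, so higher-propensity patients land in
#' more-exposed classes) and the comorbidity phecodes, creating the
#' case/exposure confounding under study; the medical-home data floor is
#' enforced by construction (intended-pass patients receive five-plus
#' diagnosis events on distinct days inside a 3-year window, intended-fail
#' patients have all events snapped to at most four distinct days).
#'
#' Dates are integer day offsets from the dataset epoch (day 0); the
#' dataset end date is `record_span_days`.  Deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with elements `dataset` (class `ehr_dataset`), `genotypes`
#'   (`genotype_matrix`), `truth` (per-patient latent labels: case status,
#'   intended exposure class, propensity, liability, floor intent) and
#'   `phecode_map` (the matching toy map).
#' @export
generate_dataset <- function(config) {
  abort_if(!inherits(config, "generator_config"), "config must be a generator_config")
  n <- config$n_patients
  end_day <- config$record_span_days

  # --- demographics -------------------------------------------------------
  demo <- with_seed(stage_seed(config$seed, "generate"), {
    age <- stats::runif(n, config$age_range_years[1], config$age_range_years[2])
    list(
      site = sample.int(config$n_sites, n, replace = TRUE),
      sex = sample(c("F", "M"), n, replace = TRUE),
      race = sample(paste0("R", 1:3), n, replace = TRUE, prob = c(0.6, 0.25, 0.15)),
      ethnicity = sample(paste0("E", 1:2), n, replace = TRUE, prob = c(0.85, 0.15)),
      birth_date = as.integer(round(end_day - age * 365.25)),
      cancer = stats::runif(n) < 0.03,
      floor_fail = stats::runif(n) < config$floor_failure_rate
    )
  })

  # --- genotypes and case liability --------------------------------------
  geno <- NULL
  if (config$n_variants > 0L) {
    geno <- with_seed(stage_seed(config$seed, "genotypes"),
                      simulate_genotypes(n, config$n_variants, config$maf_range))
    phen <- with_seed(stage_seed(config$seed, "liability"),
                      simulate_liability_phenotype(geno, config$case_prevalence,
                                                   config$n_causal,
                                                   config$heritability_liability))
    case <- phen$case
    liability <- phen$liability
  } else {
    case <- with_seed(stage_seed(config$seed, "liability"),
                      stats::runif(n) < config$case_prevalence)
    liability <- rep(NA_real_, n)
  }

  rec_lo <- pmax(0L, demo$birth_date)
  rec_hi <- rep(end_day, n)

  out <- with_seed(stage_seed(config$seed, "cohort"), {
    # --- exposure propensity and pattern class ---------------------------
    propensity <- stats::rnorm(n)
    classes <- c("none", "single", "minimal", "chronic")
    class_of <- function(p, probs) {
      classes[findInterval(p, cumsum(probs), left.open = TRUE) + 1L]
    }
    u <- stats::pnorm(propensity)
    expo_class <- character(n)
    expo_class[case]  <- class_of(u[case],  config$exposure_class_probs$case)
    expo_class[!case] <- class_of(u[!case], config$exposure_class_probs$noncase)

    rx_opioid <- realize_patterns_bulk(expo_class, rec_lo, rec_hi)
    if (nrow(rx_opioid) == 0L) {
      rx_opioid <- data.table::data.table(patient_id = integer(0), event_date = integer(0))
    }
    rx_other <- data.table::data.table(
      patient_id = seq_len(n),
      event_date = as.integer(rec_lo + floor(stats::runif(n) * (rec_hi - rec_lo + 1))))
    rx_opioid[, opioid := TRUE]
    rx_other[, opioid := FALSE]
    prescriptions <- data.table::rbindlist(list(rx_opioid, rx_other))

    # --- diagnosis events -------------------------------------------------
    # floor-fail patients: four anchor days; every event snaps to one
    anchor <- matrix(NA_integer_, nrow = n, ncol = 4L)
    nf <- sum(demo$floor_fail)
    if (nf > 0L) {
      span <- rec_hi[demo$floor_fail] - rec_lo[demo$floor_fail]
      for (k in 1:4) {
        anchor[demo$floor_fail, k] <- as.integer(
          rec_lo[demo$floor_fail] + floor(span * (k - 1) / 4) +
            floor(stats::runif(nf) * pmax(1, span / 8)))
      }
    }
    snap <- function(ids) {
      # random anchor per event for floor-fail patients
      k <- sample.int(4L, length(ids), replace = TRUE)
      anchor[cbind(ids, k)]
    }
    ev <- list()
    # filler events guaranteeing the floor for intended-pass patients:
    # six strictly increasing days inside an 890-day window
    pass <- which(!demo$floor_fail)
    if (length(pass)) {
      a <- as.integer(rec_lo[pass] +
                        floor(stats::runif(length(pass)) * (rec_hi[pass] - rec_lo[pass] - 890)))
      days <- lapply(0:5, function(j) a + 150L * j +
                       as.integer(floor(stats::runif(length(pass)) * 140)))
      ev$filler_pass <- data.table::data.table(
        patient_id = rep(pass, 6L),
        event_date = unlist(days),
        code = sample(sprintf("R%02d", 0:9), 6L * length(pass), replace = TRUE),
        code_version = "ICD10")
    }
    fail <- which(demo$floor_fail)
    if (length(fail)) {
      ev$filler_fail <- data.table::data.table(
        patient_id = rep(fail, 3L),
        event_date = c(anchor[fail, 1L], anchor[fail, 2L], anchor[fail, 3L]),
        code = sample(sprintf("R%02d", 0:9), 3L * length(fail), replace = TRUE),
        code_version = "ICD10")
    }
    place <- function(ids) {
      # event date for mapped/OUD/cancer events, respecting floor intent
      d <- integer(length(ids))
      ff <- demo$floor_fail[ids]
      if (any(ff)) d[ff] <- snap(ids[ff])
      if (any(!ff)) d[!ff] <- as.integer(
        rec_lo[ids[!ff]] + floor(stats::runif(sum(!ff)) * (rec_hi[ids[!ff]] - rec_lo[ids[!ff]] + 1)))
      d
    }
    # OUD codes for cases (dotted dialect exercises normalization)
    if (any(case)) {
      ids <- which(case)
      ev$oud <- data.table::data.table(
        patient_id = ids, event_date = place(ids),
        code = sample(c("F11.20", "304.00"), length(ids), replace = TRUE, prob = c(0.7, 0.3)),
        code_version = NA_character_)
      ev$oud[, code_version := data.table::fifelse(code == "F11.20", "ICD10", "ICD9")]
    }
    if (any(demo$cancer)) {
      ids <- which(demo$cancer)
      ev$cancer <- data.table::data.table(
        patient_id = ids, event_date = place(ids),
        code = sample(c("C50.9", "174.9"), length(ids), replace = TRUE),
        code_version = NA_character_)
      ev$cancer[, code_version := data.table::fifelse(code == "C50.9", "ICD10", "ICD9")]
    }
    # comorbidity phecodes: logistic model on case status, propensity, site
    for (cs in config$comorbidity_specs) {
      shift <- rep_len(cs$site_shift, config$n_sites)
      eta <- stats::qlogis(cs$prevalence) + cs$log_or_case * case +
        cs$log_or_exposure * propensity + shift[demo$site]
      pos <- which(stats::runif(n) < stats::plogis(eta))
      if (!length(pos)) next
      stripped <- gsub("\\.", "", cs$phecode)
      v10 <- stats::runif(length(pos)) < 0.5
      ev[[paste0("phe_", stripped)]] <- data.table::data.table(
        patient_id = pos, event_date = place(pos),
        code = ifelse(v10, paste0("Y", stripped), paste0("V", stripped)),
        code_version = ifelse(v10, "ICD10", "ICD9"))
    }
    diagnoses <- data.table::rbindlist(ev, use.names = TRUE)
    data.table::setorder(diagnoses, patient_id, event_date, code)
    data.table::setorder(prescriptions, patient_id, event_date, -opioid)
    list(diagnoses = diagnoses, prescriptions = prescriptions,
         propensity = propensity, expo_class = expo_class)
  })

  patients <- data.table::data.table(
    patient_id = seq_len(n), sex = demo$sex, race = demo$race,
    ethnicity = demo$ethnicity, birth_date = demo$birth_date, site = demo$site)

  class_label <- c(none = "unexposed", single = "single_rx",
                   minimal = "minimal", chronic = "chronic_pattern")
  truth <- data.table::data.table(
    patient_id = seq_len(n), site = demo$site, is_case = case,
    exposure_class = unname(class_label[out$expo_class]),
    propensity = out$propensity, liability = liability,
    floor_intent_pass = !demo$floor_fail, cancer = demo$cancer,
    age = age_years(demo$birth_date, end_day))

  dataset <- new_ehr_dataset(patients, out$diagnoses, out$prescriptions, end_day)
  list(dataset = dataset, genotypes = geno, truth = truth,
       phecode_map = toy_phecode_map(config$comorbidity_specs))
}

#' Construct and validate an EHR dataset container
#'
#' @param patients data.frame with columns patient_id, sex, race,
#'   ethnicity, birth_date, site.
#' @param diagnoses data.frame with columns patient_id, event_date, code,
#'   code_version.
#' @param prescriptions data.frame with columns patient_id, event_date,
#'   opioid.
#' @param dataset_end_date integer day offset of the dataset end.
#' @return an `ehr_dataset` list.
#' @export
new_ehr_dataset <- function(patients, diagnoses, prescriptions, dataset_end_date) {
  patients <- data.table::as.data.table(patients)
  diagnoses <- data.table::as.data.table(diagnoses)
  prescriptions <- data.table::as.data.table(prescriptions)
  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    abort_if(length(missing) > 0, "%s table lacks column(s): %s", what,
             paste(missing, collapse = ", "))
  }
  need(patients, c("patient_id", "sex", "race", "ethnicity", "birth_date", "site"), "patients")
  need(diagnoses, c("patient_id", "event_date", "code", "code_version"), "diagnoses")
  need(prescriptions, c("patient_id", "event_date", "opioid"), "prescriptions")
  abort_if(anyDuplicated(patients$patient_id) > 0, "duplicate patient ids")
  for (tb in list(diagnoses, prescriptions)) {
    abort_if(!all(tb$patient_id %in% patients$patient_id),
             "event table references unknown patient ids")
  }
  born <- patients$birth_date[match(diagnoses$patient_id, patients$patient_id)]
  abort_if(any(diagnoses$event_date < born | diagnoses$event_date > dataset_end_date),
           "diagnosis event dates outside [birth date, dataset end]")
  born <- patients$birth_date[match(prescriptions$patient_id, patients$patient_id)]
  abort_if(any(prescriptions$event_date < born | prescriptions$event_date > dataset_end_date),
           "prescription event dates outside [birth date, dataset end]")
  structure(list(patients = patients, diagnoses = diagnoses,
                 prescriptions = prescriptions,
                 dataset_end_date = as.integer(dataset_end_date)),
            class = "ehr_dataset")
}
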