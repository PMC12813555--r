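#' Preset run configurations
#'
#' Three problem sizes for the end-to-end pipeline:
#' * `smoke` — 2 000 patients, 20-phecode panel, 200 variants; seconds.
#' * `desk` — 30 000 patients, 20-phecode panel, 1 000 variants; the scale
#'   at which the attenuation and calibration properties are evaluated.
#' * `full` — 80 000 patients, 2 000 variants.
#'
#' The minimum-phecode-case filter scales with the preset so the power
#' filter plays the same role at every size.
#'
#' @param preset `"smoke"`, `"desk"` or `"full"`.
#' @param seed top-level integer seed; per-stage seeds are derived from it
#'   with a fixed counter scheme and recorded in the manifest.
#' @return a `run_config` list with elements `generator` (a
#'   [generator_config()]), `cohort` (a [cohort_config()]), `preset`,
#'   `seed`.
#' @export
preset_config <- function(preset = c("smoke", "desk", "full"), seed = 1L) {
  preset <- match.arg(preset)
  sizes <- list(
    smoke = list(n = 2000L,  m = 200L,  min_cases = 20L),
    desk  = list(n = 30000L, m = 1000L, min_cases = 50L),
    full  = list(n = 80000L, m = 2000L, min_cases = 100L))
  s <- sizes[[preset]]
  structure(list(
    generator = generator_config(n_patients = s$n, n_variants = s$m,
                                 n_causal = min(20L, s$m), seed = seed),
    cohort = cohort_config(min_phecode_cases = s$min_cases),
    preset = preset, seed = as.integer(seed)
  ), class = "run_config")
}

# median age of record per patient, vectorized over the diagnosis table
median_ages <- function(dataset) {
  dx <- unique(dataset$diagnoses[, .(patient_id, event_date)])
  born <- dataset$patients$birth_date[match(dx$patient_id, dataset$patients$patient_id)]
  dx[, age := (event_date - born) / 365.25]
  ma <- dx[, .(median_age = stats::median(age)), by = patient_id]
  out <- ma$median_age[match(dataset$patients$patient_id, ma$patient_id)]
  stats::setNames(out, dataset$patients$patient_id)
}

# matching frame (patient_id + exact vars + median age) for a set of ids
matching_frame <- function(dataset, ids, med_age) {
  p <- dataset$patients[match(ids, patient_id)]
  data.table::data.table(
    patient_id = p$patient_id, race = p$race, ethnicity = p$ethnicity,
    sex = p$sex, median_age = unname(med_age[as.character(ids)]))
}

# fixed-effects meta across sites of per-site summary-stat tables
meta_summary_stats <- function(stats_list) {
  all <- data.table::rbindlist(stats_list, idcol = "site")
  all <- all[is.finite(beta) & is.finite(se) & se > 0]
  all[, {
    m <- meta_fixed_effects(beta, se)
    list(effect_allele = effect_allele[1L], other_allele = other_allele[1L],
         beta = m$beta, se = m$se,
         p = max(2 * stats::pnorm(-abs(m$beta / m$se)), .Machine$double.xmin),
         maf = mean(maf), n = sum(n), q = m$q, i2 = m$i2)
  }, by = variant_id]
}

#' Run the full control-definition comparison pipeline on synthetic data
#'
#' Chains every stage of the study design: synthetic-EHR generation,
#' cohort construction for both control definitions (exposed controls
#' matched first, generic controls drawn from the remaining pool so the
#' two groups are disjoint), 4:1 exact-stratum matching on race,
#' ethnicity, sex and median age of record, phecode mapping with the
#' minimum-case filter, per-site PheWAS, cross-site fixed-effects
#' meta-analysis with heterogeneity flags, the two-definition comparison
#' report, per-site covariate-adjusted variant scans meta-analysed across
#' sites, and effect-size dilution of each definition's scan against a
#' well-powered reference scan built from the true case labels.
#'
#' Every output table is written under `out_dir` together with a
#' `manifest.json` recording the configuration, per-stage seeds, row
#' counts and MD5 hashes; a rerun with the same config and seed is
#' byte-identical.
#'
#' @param config a `run_config` from [preset_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return list with `truth`, `cohorts`, `matched`, `phewas` (per-site),
#'   `meta` (per-mode), `comparison`, `scans` (per-mode meta), `dilution`
#'   (per-mode), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  abort_if(!inherits(config, "run_config"), "config must come from preset_config()")
  gen_cfg <- config$generator
  coh_cfg <- config$cohort
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %+.1fs %s",
                                          format(Sys.time(), "%H:%M:%S"),
                                          as.numeric(difftime(Sys.time(), t0, units = "secs")),
                                          name))

  stage("generate synthetic EHR")
  gen <- generate_dataset(gen_cfg)
  dataset <- gen$dataset
  med_age <- median_ages(dataset)

  stage("build cohorts (exposed, then generic from the remaining pool)")
  coh_exposed <- build_cohorts(dataset, coh_cfg, mode = "exposed")
  matched_exposed <- match_controls(
    matching_frame(dataset, coh_exposed$case_ids, med_age),
    matching_frame(dataset, coh_exposed$eligible_control_ids, med_age),
    ratio = coh_cfg$match_ratio,
    seed = stage_seed(config$seed, "match_exposed"))
  coh_generic <- build_cohorts(dataset, coh_cfg, mode = "generic",
                               exclude_controls = matched_exposed$control_ids)
  matched_generic <- match_controls(
    matching_frame(dataset, coh_generic$case_ids, med_age),
    matching_frame(dataset, coh_generic$eligible_control_ids, med_age),
    ratio = coh_cfg$match_ratio,
    seed = stage_seed(config$seed, "match_generic"))
  matched <- list(generic = matched_generic, exposed = matched_exposed)
  cohorts <- list(generic = coh_generic, exposed = coh_exposed)

  stage("phecode mapping and per-site PheWAS")
  map <- new_phecode_map(gen$phecode_map)
  site_of <- stats::setNames(dataset$patients$site, dataset$patients$patient_id)
  phewas <- list(); metas <- list()
  for (mode in c("generic", "exposed")) {
    mc <- matched[[mode]]
    ids <- c(mc$case_ids, mc$control_ids)
    pm <- suppressMessages(build_phenotype_matrix(dataset$diagnoses, map, ids))
    pm <- filter_phecodes(pm, coh_cfg$min_phecode_cases)
    phewas[[mode]] <- run_phewas(mc, pm, site_of)
    metas[[mode]] <- meta_phewas(phewas[[mode]])
  }

  stage("comparison report")
  comparison <- compare_control_groups(metas$generic, metas$exposed,
                                       alpha = coh_cfg$alpha)

  scans <- list(); dilutions <- list(); reference <- NULL
  if (!is.null(gen$genotypes)) {
    stage("variant scans")
    truth <- gen$truth
    scan_for <- function(ids, case_ids) {
      rows <- match(ids, dataset$patients$patient_id)
      sub <- list(dosages = gen$genotypes$dosages[rows, , drop = FALSE],
                  variant_id = gen$genotypes$variant_id,
                  effect_allele = gen$genotypes$effect_allele,
                  other_allele = gen$genotypes$other_allele,
                  maf = gen$genotypes$maf,
                  obs_freq = colMeans(gen$genotypes$dosages[rows, , drop = FALSE]) / 2)
      class(sub) <- "genotype_matrix"
      case <- ids %in% case_ids
      site <- site_of[as.character(ids)]
      per_site <- lapply(sort(unique(site)), function(s) {
        sel <- site == s
        g <- sub
        g$dosages <- sub$dosages[sel, , drop = FALSE]
        g$obs_freq <- colMeans(g$dosages) / 2
        k <- min(20L, nrow(g$dosages) - 1L, ncol(g$dosages))
        pcs <- compute_pcs(g, k = k)
        covs <- make_scan_covariates(truth$age[match(ids[sel], truth$patient_id)],
                                     dataset$patients$sex[match(ids[sel], dataset$patients$patient_id)],
                                     pcs)
        run_variant_scan(g, case[sel], covs, maf_min = coh_cfg$maf_min)
      })
      meta_summary_stats(per_site)
    }
    for (mode in c("generic", "exposed")) {
      mc <- matched[[mode]]
      scans[[mode]] <- scan_for(c(mc$case_ids, mc$control_ids), mc$case_ids)
    }
    # well-powered reference: all true cases versus all non-cases
    stage("reference scan and dilution")
    reference <- scan_for(truth$patient_id, truth$patient_id[truth$is_case])
    for (mode in c("generic", "exposed")) {
      dilutions[[mode]] <- tryCatch(
        estimate_dilution(scans[[mode]], reference,
                          n_boot = 500L,
                          seed = stage_seed(config$seed, "dilution")),
        error = function(e) structure(list(error = conditionMessage(e)),
                                      class = "dilution_error"))
    }
  }

  manifest <- list(
    preset = config$preset, seed = config$seed,
    stage_seeds = lapply(stats::setNames(nm = c("generate", "match_exposed",
                                                "match_generic", "dilution")),
                         function(s) stage_seed(config$seed, s)),
    thresholds = unclass(coh_cfg)[c("pair_window_days", "third_rx_exclusion_days",
                                    "chronic_gap_days", "floor_min_codes",
                                    "floor_window_days", "min_control_age_years",
                                    "match_ratio", "min_phecode_cases", "alpha",
                                    "maf_min")],
    n_patients = gen_cfg$n_patients,
    counts = list(
      cases = length(cohorts$generic$case_ids),
      generic_controls = length(matched$generic$control_ids),
      exposed_controls = length(matched$exposed$control_ids),
      phecodes_generic = nrow(metas$generic),
      phecodes_exposed = nrow(metas$exposed),
      sig_generic = comparison$n_a, sig_exposed = comparison$n_b,
      sig_common = comparison$n_common))

  result <- list(truth = gen$truth, cohorts = cohorts, matched = matched,
                 phewas = phewas, meta = metas, comparison = comparison,
                 scans = scans, reference = reference, dilution = dilutions,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    stage("write outputs")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ehr_dataset(dataset, file.path(out_dir, "dataset"))
    write_tsv(gen$truth, file.path(out_dir, "truth.tsv"))
    data.table::fwrite(gen$phecode_map, file.path(out_dir, "phecode_map.csv"))
    for (mode in c("generic", "exposed")) {
      flags <- cohorts[[mode]]$flags
      write_tsv(flags, file.path(out_dir, sprintf("cohort_%s.tsv", mode)))
      write_tsv(matched[[mode]]$assignment,
                file.path(out_dir, sprintf("matched_%s.tsv", mode)))
      write_tsv(phewas[[mode]], file.path(out_dir, sprintf("phewas_site_%s.tsv", mode)))
      write_tsv(metas[[mode]], file.path(out_dir, sprintf("phewas_meta_%s.tsv", mode)))
      if (!is.null(scans[[mode]])) {
        write_summary_stats(scans[[mode]],
                            file.path(out_dir, sprintf("sumstats_%s.tsv", mode)))
      }
    }
    if (!is.null(reference)) {
      write_summary_stats(reference, file.path(out_dir, "sumstats_reference.tsv"))
    }
    if (nrow(comparison$differences) > 0L) {
      write_tsv(comparison$differences, file.path(out_dir, "comparison_differences.tsv"))
    }
    comp_json <- comparison[c("threshold_a", "threshold_b", "n_a", "n_b",
                              "n_common", "n_a_only", "n_b_only",
                              "attenuation_share", "note")]
    dil_json <- lapply(dilutions, function(d) {
      if (inherits(d, "dilution_error")) list(error = d$error)
      else d[c("delta_hat", "ci95", "p_vs_1", "n_variants")]
    })
    jsonlite::write_json(list(comparison = comp_json, dilution = dil_json),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10)
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          "manifest.json"))
    manifest$files <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$files) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}
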