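# Delimited-text interfaces.  All tables are TSV with header rows; floats
# are serialized with 10 significant digits so outputs are diff-able and
# bit-stable across reruns.

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  x <- data.table::as.data.table(x)
  num <- names(x)[vapply(x, is.double, logical(1))]
  if (length(num)) {
    x <- data.table::copy(x)
    x[, (num) := lapply(.SD, function(v) sprintf("%.10g", v)), .SDcols = num]
  }
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA",
                     eol = "\n", showProgress = FALSE)
  invisible(path)
}

#' Read a TSV with header validation
#'
#' Accepts LF or CRLF line endings.
#'
#' @param path input path.
#' @param required character vector of required column names.
#' @return data.table.
#' @export
read_tsv <- function(path, required = NULL) {
  abort_if(!file.exists(path), "file not found: %s", path)
  x <- data.table::fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    abort_if(length(missing) > 0, "%s lacks required column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  x
}

#' Write an EHR dataset as a directory of TSV tables
#'
#' Writes `patients.tsv`, `diagnoses.tsv`, `prescriptions.tsv` and a
#' `dataset.json` carrying the dataset end date.
#'
#' @param dataset an `ehr_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(dataset$patients, file.path(dir, "patients.tsv"))
  write_tsv(dataset$diagnoses, file.path(dir, "diagnoses.tsv"))
  write_tsv(dataset$prescriptions, file.path(dir, "prescriptions.tsv"))
  jsonlite::write_json(list(dataset_end_date = dataset$dataset_end_date),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an EHR dataset written by [write_ehr_dataset()]
#'
#' @param dir dataset directory.
#' @return an `ehr_dataset`.
#' @export
read_ehr_dataset <- function(dir) {
  pat <- read_tsv(file.path(dir, "patients.tsv"),
                  c("patient_id", "sex", "race", "ethnicity", "birth_date", "site"))
  dx <- read_tsv(file.path(dir, "diagnoses.tsv"),
                 c("patient_id", "event_date", "code", "code_version"))
  rx <- read_tsv(file.path(dir, "prescriptions.tsv"),
                 c("patient_id", "event_date", "opioid"))
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"))
  new_ehr_dataset(pat, dx, rx, meta$dataset_end_date)
}

#' Read a one-code-per-line ICD code list
#'
#' Blank lines and `#` comments are ignored; codes are normalized.
#'
#' @param path text file path.
#' @return character vector of normalized codes.
#' @export
read_code_list <- function(path) {
  abort_if(!file.exists(path), "code list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  normalize_icd(x)
}

#' Write variant summary statistics in the common GWAS dialect
#'
#' Columns SNP, A1 (effect allele), A2, BETA, SE, P, MAF, N.
#'
#' @param stats `summary_stats` table from [run_variant_scan()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.table::data.table(
    SNP = stats$variant_id, A1 = stats$effect_allele, A2 = stats$other_allele,
    BETA = stats$beta, SE = stats$se, P = stats$p, MAF = stats$maf, N = stats$n)
  write_tsv(out, path)
}

#' Read variant summary statistics in the common GWAS dialect
#'
#' @param path input path (columns SNP, A1, A2, BETA, SE, P; MAF and N
#'   optional).
#' @return `summary_stats` data.table with package-internal column names.
#' @export
read_summary_stats <- function(path) {
  x <- read_tsv(path, c("SNP", "A1", "A2", "BETA", "SE", "P"))
  data.table::data.table(
    variant_id = as.character(x$SNP),
    effect_allele = toupper(x$A1), other_allele = toupper(x$A2),
    beta = as.numeric(x$BETA), se = as.numeric(x$SE), p = as.numeric(x$P),
    maf = if ("MAF" %in% names(x)) as.numeric(x$MAF) else NA_real_,
    n = if ("N" %in% names(x)) as.integer(x$N) else NA_integer_)
}

#' Read a generator configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [generator_config()];
#' `comorbidity_specs` is a list of records with keys phecode, prevalence,
#' log_or_case, log_or_exposure, site_shift.
#'
#' @param path YAML (or JSON) file path.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  abort_if(!file.exists(path), "config file not found: %s", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$comorbidity_specs)) {
    raw$comorbidity_specs <- lapply(raw$comorbidity_specs, function(cs) {
      do.call(comorbidity_spec, cs)
    })
  }
  if (!is.null(raw$exposure_class_probs)) {
    raw$exposure_class_probs <- lapply(raw$exposure_class_probs, unlist)
  }
  do.call(generator_config, raw)
}
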