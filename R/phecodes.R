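#' Load a phecode map from CSV
#'
#' Accepts either a long layout with columns `code`, `version` (ICD9/ICD10)
#' and `phecode`, or the published Phecode Map 1.2 dialect where the code
#' column is named `icd9` or `icd10` (the column name carrying the
#' version).  Codes are normalized with [normalize_icd()]; identical
#' duplicate rows collapse; a (code, version) pair mapping to two phecodes
#' is an error.
#'
#' @param path CSV file path.
#' @return a `phecode_map`: data.table with columns `code`, `version`,
#'   `phecode`.
#' @export
load_phecode_map <- function(path) {
  abort_if(!file.exists(path), "phecode map not found: %s", path)
  raw <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  if (nrow(raw) == 0L) {
    return(new_phecode_map(data.table::data.table(
      code = character(0), version = character(0), phecode = character(0))))
  }
  nms <- tolower(names(raw))
  data.table::setnames(raw, nms)
  phe_col <- intersect(c("phecode", "phewas_code"), nms)[1]
  abort_if(is.na(phe_col), "no phecode column found in %s", path)
  if (all(c("code", "version") %in% nms)) {
    map <- raw[, .(code = code, version = toupper(version), phecode = get(phe_col))]
  } else {
    pieces <- list()
    for (v in c("icd9", "icd10")) {
      if (v %in% nms) {
        pieces[[v]] <- data.table::data.table(
          code = raw[[v]], version = toupper(v), phecode = raw[[phe_col]])
      }
    }
    abort_if(length(pieces) == 0L,
             "no ICD code column (code/icd9/icd10) found in %s", path)
    map <- data.table::rbindlist(pieces)
  }
  new_phecode_map(map)
}

#' Construct and validate a phecode map from a table
#'
#' Validates and normalizes an in-memory map (columns `code`, `version`,
#' `phecode`), applying the same dialect rules as [load_phecode_map()].
#'
#' @param map data.frame with columns `code`, `version` (ICD9/ICD10) and
#'   `phecode`.
#' @return a `phecode_map` data.table.
#' @export
new_phecode_map <- function(map) {
  map <- data.table::as.data.table(map)
  map[, code := normalize_icd(code)]
  map[, version := toupper(version)]
  abort_if(!all(map$version %in% c("ICD9", "ICD10")),
           "version column must be ICD9 or ICD10")
  abort_if(!all(grepl("^[0-9]+(\\.[0-9]+)?$", map$phecode)),
           "phecode labels must be numeric-dotted strings")
  map <- unique(map)
  dup <- map[, .N, by = .(code, version)][N > 1L]
  abort_if(nrow(dup) > 0,
           "conflicting phecode map entries for: %s",
           paste(dup$code, collapse = ", "))
  data.table::setattr(map, "class", c("phecode_map", class(map)))
  map[]
}

#' Map diagnosis events to a patient-by-phecode indicator matrix
#'
#' An indicator is TRUE iff the patient has at least one diagnosis event
#' whose (code, version) maps to the phecode — idempotent under event
#' duplication.  Unmapped ICD codes are dropped and their count reported
#' in a message.  Rows are restricted to the supplied cohort members; a
#' patient with no mappable codes has an all-FALSE row.
#'
#' @param diagnoses diagnosis-event table (patient_id, event_date, code,
#'   code_version).
#' @param map a `phecode_map`.
#' @param patient_ids cohort members (matrix rows, in this order).
#' @param rollup if TRUE, a phecode also sets its integer-prefix parent
#'   (e.g. 296.20 implies 296); off by default.
#' @return logical matrix patients x phecodes with dimnames.
#' @export
build_phenotype_matrix <- function(diagnoses, map, patient_ids, rollup = FALSE) {
  dx <- data.table::as.data.table(diagnoses)[patient_id %in% patient_ids]
  dx[, code := normalize_icd(code)]
  hit <- merge(dx, map, by.x = c("code", "code_version"),
               by.y = c("code", "version"), allow.cartesian = TRUE)
  n_unmapped <- nrow(dx) - nrow(hit)
  if (n_unmapped > 0) {
    message(sprintf("build_phenotype_matrix: dropped %d unmapped diagnosis events",
                    n_unmapped))
  }
  phecodes <- sort(unique(map$phecode))
  mat <- matrix(FALSE, nrow = length(patient_ids), ncol = length(phecodes),
                dimnames = list(as.character(patient_ids), phecodes))
  if (nrow(hit) > 0L) {
    mat[cbind(match(hit$patient_id, patient_ids), match(hit$phecode, phecodes))] <- TRUE
  }
  if (rollup && length(phecodes) > 0L) {
    parents <- sub("\\..*$", "", phecodes)
    for (p in unique(parents)) {
      kids <- which(parents == p & phecodes != p)
      tgt <- which(phecodes == p)
      if (length(tgt) == 1L && length(kids) > 0L) {
        mat[, tgt] <- mat[, tgt] | rowSums(mat[, kids, drop = FALSE]) > 0L
      }
    }
  }
  mat
}

#' Drop phecodes with too few positive patients
#'
#' Keeps phecodes with at least `min_cases` positive patients among the
#' analysed set — the minimum-case power filter.  Monotone: raising
#' `min_cases` never adds a phecode.
#'
#' @param matrix logical patients x phecodes matrix.
#' @param min_cases minimum positive count.
#' @return the filtered matrix (possibly zero columns).
#' @export
filter_phecodes <- function(matrix, min_cases) {
  abort_if(!(is.infinite(min_cases) || is_count(min_cases, 0L)),
           "min_cases must be a count (Inf allowed)")
  matrix[, colSums(matrix) >= min_cases, drop = FALSE]
}
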