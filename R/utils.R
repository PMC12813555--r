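# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize an ICD code string for comparison
#'
#' ICD-9 and ICD-10 source files differ in dot conventions and case; codes
#' are compared after stripping dots and whitespace and upper-casing, with
#' the ICD version tag kept separate.
#'
#' @param code character vector of ICD codes.
#' @return character vector of normalized codes.
#' @export
normalize_icd <- function(code) {
  toupper(gsub("[. ]", "", as.character(code)))
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x) &&
    x >= min && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Derive a child RNG seed from a base seed and a stage label.  Counter-based:
# each stage has a fixed offset so stages can be rerun in isolation with the
# same stream.  Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(
    generate = 11L, genotypes = 23L, liability = 37L, cohort = 53L,
    match_exposed = 67L, match_generic = 79L, phewas = 97L,
    scan = 113L, dilution = 131L, reference = 149L
  )
  off <- offsets[[stage]]
  abort_if(is.null(off), "unknown pipeline stage '%s'", stage)
  (as.integer(seed) * 1009L + off) %% 2147483647L
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's random-number stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
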