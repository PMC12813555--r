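# internal: 2x2 log-odds-ratio machinery shared by fit_logistic_assoc and
# the vectorized PheWAS.  For a saturated binary-binary logistic model the
# MLE is the cross-product log OR with Wald SE sqrt(sum of reciprocal
# cells); a zero cell triggers the 0.5 continuity correction with a flag.
logodds_2x2 <- function(a, b, c, d) {
  fallback <- (a == 0L | b == 0L | c == 0L | d == 0L)
  a <- a + 0.5 * fallback; b <- b + 0.5 * fallback
  c <- c + 0.5 * fallback; d <- d + 0.5 * fallback
  beta <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(beta = beta, se = se, fallback = fallback)
}

wald_row <- function(beta, se) {
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p[p == 0] <- .Machine$double.xmin   # keep p in (0, 1]
  list(p = p, or_ = exp(beta),
       ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se))
}

#' Logistic association between a binary outcome and a binary predictor
#'
#' Maximum-likelihood logistic fit of `outcome` on `predictor` (plus
#' optional covariates).  With no covariates the MLE equals the 2x2
#' cross-product log odds ratio and is computed in closed form; with
#' covariates [stats::glm()] is used.  Separation or non-convergence falls
#' back to the 0.5-continuity-corrected 2x2 estimate with the `fallback`
#' flag set.  A constant outcome yields a structured skip record rather
#' than an error.
#'
#' @param outcome logical vector.
#' @param predictor logical vector.
#' @param covariates optional numeric matrix of adjustment covariates.
#' @param phenotype_id optional label carried into the result.
#' @param site optional site label carried into the result.
#' @return one-row data.table with columns phenotype_id, site, beta, se,
#'   p, or_, ci_lo, ci_hi, n_case, n_control, fallback, skipped.
#' @export
fit_logistic_assoc <- function(outcome, predictor, covariates = NULL,
                               phenotype_id = NA_character_, site = NA) {
  outcome <- as.logical(outcome)
  predictor <- as.logical(predictor)
  abort_if(length(outcome) != length(predictor),
           "outcome and predictor lengths differ")
  n_case <- sum(outcome); n_control <- sum(!outcome)
  skip <- function() data.table::data.table(
    phenotype_id = phenotype_id, site = site, beta = NA_real_, se = NA_real_,
    p = NA_real_, or_ = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    n_case = n_case, n_control = n_control, fallback = FALSE, skipped = TRUE)
  if (n_case == 0L || n_control == 0L) return(skip())
  if (all(predictor) || !any(predictor)) return(skip())

  fallback <- FALSE
  if (is.null(covariates)) {
    a <- sum(outcome & predictor); b <- sum(outcome & !predictor)
    c <- sum(!outcome & predictor); d <- sum(!outcome & !predictor)
    est <- logodds_2x2(a, b, c, d)
    beta <- est$beta; se <- est$se; fallback <- est$fallback
  } else {
    dat <- data.frame(.y = as.numeric(outcome),
                      predictor = as.numeric(predictor), covariates)
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                       family = stats::binomial()))
    sm <- suppressWarnings(summary(fit)$coefficients)
    co <- sm["predictor", "Estimate"]
    se <- sm["predictor", "Std. Error"]
    ok <- isTRUE(fit$converged) && is.finite(co) && is.finite(se) &&
      abs(co) < 15 && se < 100
    if (ok) {
      beta <- unname(co)
    } else {
      # separation or non-convergence: continuity-corrected marginal 2x2
      a <- sum(outcome & predictor); b <- sum(outcome & !predictor)
      c <- sum(!outcome & predictor); d <- sum(!outcome & !predictor)
      beta <- log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
      se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (c + 0.5) + 1 / (d + 0.5))
      fallback <- TRUE
    }
  }
  w <- wald_row(beta, se)
  data.table::data.table(
    phenotype_id = phenotype_id, site = site, beta = beta, se = se,
    p = w$p, or_ = w$or_, ci_lo = w$ci_lo, ci_hi = w$ci_hi,
    n_case = n_case, n_control = n_control,
    fallback = as.logical(fallback), skipped = FALSE)
}

#' Per-site PheWAS over a phenotype matrix
#'
#' One logistic association per phecode per site: outcome = phecode
#' indicator, predictor = case status, fitted as unconditional logistic
#' regression on the matched individuals (no covariates beyond the
#' matching itself).  Computed via the closed-form 2x2 MLE per phecode,
#' with the continuity-corrected fallback on zero cells (separation).
#' Phecodes constant within a site become structured skip rows.
#'
#' @param matched a `matched_cohort` from [match_controls()].
#' @param pheno_matrix logical patients x phecodes matrix with patient ids
#'   as rownames (see [build_phenotype_matrix()]).
#' @param patient_site named vector (or vector indexed like
#'   `rownames(pheno_matrix)`) giving each patient's site.
#' @return data.table of per-phecode, per-site association rows (schema of
#'   [fit_logistic_assoc()]).
#' @export
run_phewas <- function(matched, pheno_matrix, patient_site) {
  if (ncol(pheno_matrix) == 0L) {
    return(data.table::data.table(
      phenotype_id = character(0), site = integer(0), beta = numeric(0),
      se = numeric(0), p = numeric(0), or_ = numeric(0), ci_lo = numeric(0),
      ci_hi = numeric(0), n_case = integer(0), n_control = integer(0),
      fallback = logical(0), skipped = logical(0)))
  }
  ids <- c(matched$case_ids, setdiff(matched$control_ids, matched$case_ids))
  rows <- match(as.character(ids), rownames(pheno_matrix))
  abort_if(anyNA(rows), "phenotype matrix lacks rows for %d cohort members",
           sum(is.na(rows)))
  is_case <- ids %in% matched$case_ids
  site <- patient_site[as.character(ids)]
  out <- vector("list", 0L)
  for (s in sort(unique(site))) {
    sel <- which(site == s)
    M <- pheno_matrix[rows[sel], , drop = FALSE]
    y <- is_case[sel]
    nc <- sum(y); nk <- sum(!y)
    a <- colSums(M[y, , drop = FALSE])        # phe+ cases
    b <- colSums(M[!y, , drop = FALSE])       # phe+ controls
    cc <- nc - a                              # phe- cases
    d <- nk - b                               # phe- controls
    skipped <- (a + b == 0L) | (cc + d == 0L)
    est <- logodds_2x2(a, b, cc, d)
    w <- wald_row(est$beta, est$se)
    dt <- data.table::data.table(
      phenotype_id = colnames(pheno_matrix), site = s,
      beta = est$beta, se = est$se, p = w$p, or_ = w$or_,
      ci_lo = w$ci_lo, ci_hi = w$ci_hi,
      n_case = as.integer(a + b), n_control = as.integer(cc + d),
      fallback = est$fallback, skipped = skipped)
    dt[skipped == TRUE, c("beta", "se", "p", "or_", "ci_lo", "ci_hi") := NA_real_]
    out[[length(out) + 1L]] <- dt
  }
  data.table::rbindlist(out)
}
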