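#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-site estimates with weights \eqn{w_i = 1/se_i^2}: pooled beta
#' \eqn{\sum w_i b_i / \sum w_i}, pooled SE \eqn{\sqrt{1/\sum w_i}},
#' Cochran's \eqn{Q = \sum w_i (b_i - \bar b)^2} on \eqn{k - 1} degrees of
#' freedom, \eqn{I^2 = \max(0, (Q - df)/Q)} (0 when Q = 0), two-sided
#' normal p.  Estimates with \eqn{I^2 > 0.75} are flagged as significantly
#' heterogeneous.  A single study passes through unchanged with Q = 0.
#'
#' @param beta numeric vector of per-study log-odds estimates.
#' @param se numeric vector of matching standard errors (all > 0).
#' @param i2_threshold heterogeneity flag threshold on the 0-1 proportion
#'   scale (default 0.75).
#' @return a `meta_result` list: beta, se, p, q, df, i2, het_flag, k.
#' @export
meta_fixed_effects <- function(beta, se, i2_threshold = 0.75) {
  keep <- is.finite(beta) & is.finite(se)
  beta <- beta[keep]; se <- se[keep]
  k <- length(beta)
  abort_if(k < 1L, "meta-analysis needs at least one study")
  abort_if(length(se) != k || any(se <= 0), "se must be positive and match beta")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  q <- if (k == 1L) 0 else sum(w * (beta - b)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  z <- b / s
  p <- 2 * stats::pnorm(-abs(z))
  p <- max(p, .Machine$double.xmin)
  structure(list(beta = b, se = s, p = p, q = q, df = df, i2 = i2,
                 het_flag = i2 > i2_threshold, k = k),
            class = "meta_result")
}

#' Meta-analyse a per-site PheWAS table across sites
#'
#' Applies [meta_fixed_effects()] per phenotype over the site-level rows
#' produced by [run_phewas()]; skipped site rows are dropped, and a
#' phenotype with no usable site estimate is dropped entirely.
#'
#' @param results per-site association data.table (schema of
#'   [run_phewas()]).
#' @param i2_threshold heterogeneity flag threshold.
#' @return data.table with one row per phenotype: phenotype_id, beta, se,
#'   p, or_, ci_lo, ci_hi, q, df, i2, het_flag, k.
#' @export
meta_phewas <- function(results, i2_threshold = 0.75) {
  res <- data.table::as.data.table(results)[skipped == FALSE & is.finite(beta)]
  if (nrow(res) == 0L) {
    return(data.table::data.table(
      phenotype_id = character(0), beta = numeric(0), se = numeric(0),
      p = numeric(0), or_ = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0),
      q = numeric(0), df = integer(0), i2 = numeric(0), het_flag = logical(0),
      k = integer(0)))
  }
  res[, {
    m <- meta_fixed_effects(beta, se, i2_threshold)
    list(beta = m$beta, se = m$se, p = m$p, or_ = exp(m$beta),
         ci_lo = exp(m$beta - 1.96 * m$se), ci_hi = exp(m$beta + 1.96 * m$se),
         q = m$q, df = as.integer(m$df), i2 = m$i2, het_flag = m$het_flag,
         k = as.integer(m$k))
  }, by = phenotype_id]
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise significance level.
#' @return per-test p-value threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  abort_if(!is_count(n_tests, 1L), "n_tests must be >= 1")
  abort_if(!(is_prob(alpha) && alpha > 0), "alpha must be in (0,1]")
  alpha / n_tests
}

#' Compare the PheWAS results of two control definitions
#'
#' Given the meta-analysed PheWAS of cases versus control group A
#' (generic) and versus control group B (exposed), computes each
#' analysis's own Bonferroni threshold, the significant sets and their
#' overlap, a per-common-phecode effect-difference z-test
#' \eqn{z = (b_A - b_B)/\sqrt{se_A^2 + se_B^2}} with Bonferroni correction
#' over the common phecodes, and the attenuation share: the fraction of
#' common significant phecodes whose log-odds magnitude is larger against
#' group A than against group B.
#'
#' The difference test ignores the positive correlation induced by the
#' shared cases between the two analyses and is therefore
#' anti-conservative; this is recorded in the report.
#'
#' @param meta_a,meta_b meta-analysed PheWAS tables (see [meta_phewas()])
#'   for the two control definitions.
#' @param alpha family-wise significance level for each analysis.
#' @return a `comparison_report` list: thresholds, significant phecode
#'   sets and counts, the per-common-phecode difference table, and
#'   `attenuation_share`.
#' @export
compare_control_groups <- function(meta_a, meta_b, alpha = 0.05) {
  meta_a <- data.table::as.data.table(meta_a)
  meta_b <- data.table::as.data.table(meta_b)
  thr_a <- bonferroni_threshold(max(1L, nrow(meta_a)), alpha)
  thr_b <- bonferroni_threshold(max(1L, nrow(meta_b)), alpha)
  sig_a <- meta_a$phenotype_id[meta_a$p < thr_a]
  sig_b <- meta_b$phenotype_id[meta_b$p < thr_b]
  common <- intersect(sig_a, sig_b)

  j <- merge(meta_a[phenotype_id %in% common,
                    .(phenotype_id, beta_a = beta, se_a = se)],
             meta_b[phenotype_id %in% common,
                    .(phenotype_id, beta_b = beta, se_b = se)],
             by = "phenotype_id")
  if (nrow(j) > 0L) {
    j[, z := (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)]
    j[, p_diff := 2 * stats::pnorm(-abs(z))]
    j[, p_diff_bonf := pmin(1, p_diff * .N)]
    j[, attenuated := abs(beta_a) > abs(beta_b)]
    attenuation_share <- mean(j$attenuated)
  } else {
    attenuation_share <- NA_real_
  }
  structure(list(
    threshold_a = thr_a, threshold_b = thr_b,
    sig_a = sig_a, sig_b = sig_b,
    n_a = length(sig_a), n_b = length(sig_b),
    n_common = length(common),
    n_a_only = length(setdiff(sig_a, sig_b)),
    n_b_only = length(setdiff(sig_b, sig_a)),
    differences = j,
    attenuation_share = attenuation_share,
    note = "effect-difference z ignores shared-case correlation (anti-conservative)"
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Control-definition comparison\n")
  cat(sprintf("  significant vs A: %d (threshold %.3g)\n", x$n_a, x$threshold_a))
  cat(sprintf("  significant vs B: %d (threshold %.3g)\n", x$n_b, x$threshold_b))
  cat(sprintf("  common: %d | A-only: %d | B-only: %d\n",
              x$n_common, x$n_a_only, x$n_b_only))
  cat(sprintf("  attenuation share (|logOR_A| > |logOR_B|): %.3f\n",
              x$attenuation_share))
  invisible(x)
}
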