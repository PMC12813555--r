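#' Align two summary-statistic tables on shared variants
#'
#' Inner join on variant id with allele harmonization: when the study's
#' effect allele equals the reference's other allele and vice versa, the
#' study beta sign is flipped; strand-ambiguous A/T and C/G variants are
#' dropped and counted, as are variants whose allele sets do not match.
#'
#' @param study,ref `summary_stats` tables (columns variant_id,
#'   effect_allele, other_allele, beta, se, p).
#' @return list with `table` (variant_id, beta_study, se_study, beta_ref,
#'   se_ref, flipped), `n_dropped_ambiguous`, `n_dropped_mismatch`.
#' @export
align_variants <- function(study, ref) {
  study <- data.table::as.data.table(study)
  ref <- data.table::as.data.table(ref)
  ambiguous <- function(a1, a2) {
    (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
      (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
  }
  j <- merge(
    study[, .(variant_id, s_a1 = effect_allele, s_a2 = other_allele,
              beta_study = beta, se_study = se)],
    ref[, .(variant_id, r_a1 = effect_allele, r_a2 = other_allele,
            beta_ref = beta, se_ref = se)],
    by = "variant_id")
  amb <- ambiguous(j$s_a1, j$s_a2) | ambiguous(j$r_a1, j$r_a2)
  n_amb <- sum(amb)
  j <- j[!amb]
  same <- j$s_a1 == j$r_a1 & j$s_a2 == j$r_a2
  swapped <- j$s_a1 == j$r_a2 & j$s_a2 == j$r_a1
  n_mis <- sum(!(same | swapped))
  j <- j[same | swapped]
  j[, flipped := s_a1 == r_a2]
  j[flipped == TRUE, beta_study := -beta_study]
  list(table = j[, .(variant_id, beta_study, se_study, beta_ref, se_ref, flipped)],
       n_dropped_ambiguous = n_amb, n_dropped_mismatch = n_mis)
}

#' Estimate relative effect-size dilution against a reference
#'
#' Models the study betas as the reference betas attenuated by a common
#' multiplicative dilution, \eqn{\beta_{study,j} \approx \beta_{ref,j} /
#' \delta}, and estimates \eqn{1/\delta} as a weighted through-origin
#' errors-in-variables (Deming) regression slope of the study betas on the
#' reference betas, with per-variant weights \eqn{1/se_{study,j}^2} and
#' error-variance ratio \eqn{\lambda} taken from the two sets' reported
#' standard errors.  Both sets of betas are noisy estimates, so an
#' ordinary through-origin slope would be attenuated by the reference-side
#' noise (classical regression dilution); the errors-in-variables slope
#' removes that bias, reduces to the ordinary slope as the reference noise
#' vanishes, is exactly 1 when a study is compared with itself, and is
#' exactly reciprocal under exchange of the two inputs (for equal error
#' scales).  A dilution above 1 means the study's effects are attenuated
#' relative to the reference — the signature of phenotype
#' misclassification; the reference has dilution 1 by construction.  The
#' confidence interval and the test against \eqn{\delta = 1} come from a
#' percentile bootstrap over variants.
#'
#' @param study,ref `summary_stats` tables (see [align_variants()]).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param min_variants minimum aligned variants required.
#' @param conf confidence level for the percentile interval.
#' @return a `dilution_result`: delta_hat, ci95, p_vs_1, n_variants,
#'   n_boot, n_dropped_ambiguous, n_dropped_mismatch.
#' @export
estimate_dilution <- function(study, ref, n_boot = 1000L, seed = 1L,
                              min_variants = 50L, conf = 0.95) {
  al <- align_variants(study, ref)
  tab <- al$table
  abort_if(nrow(tab) < min_variants,
           "only %d aligned variants; need at least %d", nrow(tab), min_variants)
  # weighted through-origin Deming slope: bs = slope * br with independent
  # errors of known variance ratio lambda = var(e_study)/var(e_ref)
  slope_of <- function(bs, br, w, lambda) {
    sxx <- sum(w * br^2); syy <- sum(w * bs^2); sxy <- sum(w * bs * br)
    if (sxy == 0) return(NA_real_)
    (syy - lambda * sxx + sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
      (2 * sxy)
  }
  w <- 1 / tab$se_study^2
  lambda <- sum(w * tab$se_study^2) / sum(w * tab$se_ref^2)
  slope <- slope_of(tab$beta_study, tab$beta_ref, w, lambda)
  abort_if(!is.finite(slope) || slope <= 0,
           "no shared signal: weighted slope is non-positive")
  delta <- 1 / slope

  boot <- with_seed(seed, {
    n <- nrow(tab)
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      lam_b <- sum(w[i] * tab$se_study[i]^2) / sum(w[i] * tab$se_ref[i]^2)
      s <- slope_of(tab$beta_study[i], tab$beta_ref[i], w[i], lam_b)
      if (is.finite(s) && s > 0) 1 / s else NA_real_
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(a, 1 - a)))
  p_vs_1 <- min(1, 2 * min(mean(boot <= 1), mean(boot >= 1)))
  structure(list(delta_hat = delta, ci95 = ci, p_vs_1 = p_vs_1,
                 n_variants = nrow(tab), n_boot = length(boot),
                 n_dropped_ambiguous = al$n_dropped_ambiguous,
                 n_dropped_mismatch = al$n_dropped_mismatch),
            class = "dilution_result")
}

#' @export
print.dilution_result <- function(x, ...) {
  cat(sprintf("Effect-size dilution: %.3f (95%% CI %.3f-%.3f), p vs 1 = %.3g, %d variants\n",
              x$delta_hat, x$ci95[1], x$ci95[2], x$p_vs_1, x$n_variants))
  invisible(x)
}
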