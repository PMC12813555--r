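#' Principal components of a genotype matrix
#'
#' Top-k left singular scores of the column-standardized dosage matrix
#' (zero-variance variants dropped).  When the matrix holds more than
#' `max_variants` variants, an evenly spaced subset is used — the usual
#' pruned-subset practice for ancestry PCs, since PCs for covariate
#' adjustment do not need every variant.  Scores are deterministic up to
#' sign.
#'
#' @param genotypes a `genotype_matrix`.
#' @param k number of components (0 allowed; k <= min(n, m)).
#' @param max_variants variant-subset cap for the decomposition.
#' @return numeric n x k score matrix (columns PC1..PCk).
#' @export
compute_pcs <- function(genotypes, k = 20L, max_variants = 500L) {
  n <- nrow(genotypes$dosages)
  m <- ncol(genotypes$dosages)
  abort_if(!is_count(k, 0L) || k > min(n, m), "k must satisfy 0 <= k <= min(n, m)")
  if (k == 0L) return(matrix(numeric(0), nrow = n, ncol = 0L))
  idx <- if (m > max_variants) {
    unique(round(seq(1L, m, length.out = max_variants)))
  } else seq_len(m)
  X <- genotypes$dosages[, idx, drop = FALSE]
  mu <- colMeans(X)
  sd <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  keep <- sd > 0
  if (!any(keep)) return(matrix(0, nrow = n, ncol = k,
                                dimnames = list(NULL, paste0("PC", seq_len(k)))))
  X <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd[keep], "/")
  k <- min(k, ncol(X))
  # eigen-decomposition of the smaller Gram matrix
  cp <- crossprod(X)
  ev <- eigen(cp, symmetric = TRUE)
  scores <- X %*% ev$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Build the standard variant-scan covariate matrix
#'
#' Age, sex, age-by-sex interaction, age squared and the leading genotype
#' principal components — the conventional adjustment set for an EHR-based
#' variant association scan.
#'
#' @param age numeric age vector (years).
#' @param sex character/factor vector; the indicator is `sex == "M"`.
#' @param pcs optional PC score matrix from [compute_pcs()].
#' @return numeric covariate matrix.
#' @export
make_scan_covariates <- function(age, sex, pcs = NULL) {
  sexm <- as.numeric(sex == "M")
  X <- cbind(age = age, sex = sexm, age_sex = age * sexm, age2 = age^2)
  if (!is.null(pcs) && ncol(pcs) > 0L) X <- cbind(X, pcs)
  X
}

#' Covariate-adjusted per-variant association scan
#'
#' Drops variants with minor allele frequency below `maf_min`, then tests
#' each remaining variant for association with case status under a
#' logistic model adjusted for the covariates.  The default `"score"`
#' method fits the covariate-only null model once and applies the
#' efficient-score test per variant (the vectorized large-scale approach;
#' the reported beta is the one-step approximation U/V with SE
#' \eqn{1/\sqrt V}, accurate in the small-effect regime).  Method
#' `"wald"` fits a full logistic model per variant.
#'
#' @param genotypes a `genotype_matrix`.
#' @param case logical case-status vector (length n).
#' @param covariates numeric covariate matrix (e.g.
#'   [make_scan_covariates()]); `NULL` for an intercept-only null.
#' @param maf_min minor-allele-frequency floor (observed frequency).
#' @param method `"score"` (default) or `"wald"`.
#' @return a `summary_stats` data.table: variant_id, effect_allele,
#'   other_allele, beta, se, p, maf, n.
#' @export
run_variant_scan <- function(genotypes, case, covariates = NULL,
                             maf_min = 0.05, method = c("score", "wald")) {
  method <- match.arg(method)
  n <- nrow(genotypes$dosages)
  abort_if(length(case) != n, "case vector must match genotype rows")
  y <- as.numeric(case)
  abort_if(sum(y) == 0 || sum(y) == n, "both case and control individuals required")
  maf <- pmin(genotypes$obs_freq, 1 - genotypes$obs_freq)
  keep <- which(maf >= maf_min & maf > 0)
  empty <- data.table::data.table(
    variant_id = character(0), effect_allele = character(0),
    other_allele = character(0), beta = numeric(0), se = numeric(0),
    p = numeric(0), maf = numeric(0), n = integer(0))
  if (length(keep) == 0L) return(empty)
  G <- genotypes$dosages[, keep, drop = FALSE]
  Z <- cbind(intercept = rep(1, n), covariates)

  if (method == "score") {
    null_fit <- suppressWarnings(
      stats::glm.fit(Z, y, family = stats::binomial()))
    mu <- null_fit$fitted.values
    w <- mu * (1 - mu)
    U <- crossprod(G, y - mu)[, 1L]
    GtWZ <- crossprod(G, Z * w)
    ZtWZ <- crossprod(Z, Z * w)
    M <- solve(ZtWZ)
    V <- colSums(G^2 * w) - rowSums((GtWZ %*% M) * GtWZ)
    ok <- V > 1e-12
    beta <- ifelse(ok, U / V, NA_real_)
    se <- ifelse(ok, 1 / sqrt(V), NA_real_)
    chi2 <- ifelse(ok, U^2 / V, NA_real_)
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  } else {
    beta <- se <- p <- rep(NA_real_, length(keep))
    for (j in seq_along(keep)) {
      dat <- data.frame(.y = y, g = G[, j])
      if (!is.null(covariates)) dat <- cbind(dat, covariates)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                         family = stats::binomial()))
      sm <- suppressWarnings(summary(fit)$coefficients)
      if ("g" %in% rownames(sm)) {
        beta[j] <- sm["g", "Estimate"]
        se[j] <- sm["g", "Std. Error"]
        p[j] <- sm["g", "Pr(>|z|)"]
      }
    }
  }
  data.table::data.table(
    variant_id = genotypes$variant_id[keep],
    effect_allele = genotypes$effect_allele[keep],
    other_allele = genotypes$other_allele[keep],
    beta = as.numeric(beta), se = as.numeric(se),
    p = pmax(as.numeric(p), .Machine$double.xmin),
    maf = maf[keep], n = n)
}

#' Genomic inflation factor
#'
#' \eqn{\lambda = \mathrm{median}(\chi^2_1)/0.4549364}, the median of the
#' association chi-square statistics (obtained from the p-values through
#' the upper-tail chi-square quantile) divided by the null chi-square
#' median.  A well-calibrated scan has \eqn{\lambda \approx 1}.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric lambda.
#' @export
genomic_inflation <- function(p) {
  p <- p[is.finite(p)]
  abort_if(length(p) == 0L, "no p-values supplied")
  abort_if(any(p <= 0 | p > 1), "p-values must lie in (0, 1]")
  chi2 <- stats::qchisq(p, df = 1L, lower.tail = FALSE)
  stats::median(chi2) / stats::qchisq(0.5, df = 1L)
}
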