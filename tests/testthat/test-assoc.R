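mk_2x2 <- function(a, b, c, d) {
  # outcome x predictor cell layout: a = y1x1, b = y1x0, c = y0x1, d = y0x0
  list(outcome = rep(c(TRUE, TRUE, FALSE, FALSE), times = c(a, b, c, d)),
       predictor = rep(c(TRUE, FALSE, TRUE, FALSE), times = c(a, b, c, d)))
}

test_that("no-covariate logistic fit equals the 2x2 cross-product", {
  v <- mk_2x2(10, 90, 5, 95)
  fit <- fit_logistic_assoc(v$outcome, v$predictor)
  expect_equal(fit$or_, (10 * 95) / (90 * 5), tolerance = 1e-10)
  expect_equal(fit$beta, log(2.1111), tolerance = 1e-4)
  expect_false(fit$fallback)
  expect_true(fit$ci_lo < fit$or_ && fit$or_ < fit$ci_hi)
})

test_that("closed form agrees with a maximum-likelihood glm on random tables", {
  set.seed(6)
  for (i in 1:200) {
    cells <- rpois(4, 30) + 1L
    v <- mk_2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic_assoc(v$outcome, v$predictor)
    g <- glm(v$outcome ~ v$predictor, family = binomial(),
             control = glm.control(epsilon = 1e-12))
    expect_equal(fit$beta, unname(coef(g)[2]), tolerance = 1e-6)
    expect_equal(fit$se, unname(summary(g)$coefficients[2, 2]), tolerance = 1e-6)
  }
})

test_that("zero cells fall back to the continuity-corrected estimate", {
  v <- mk_2x2(0, 50, 30, 20)
  fit <- fit_logistic_assoc(v$outcome, v$predictor)
  expect_true(fit$fallback)
  expect_true(is.finite(fit$or_) && fit$or_ > 0)
  expect_true(fit$p > 0 && fit$p <= 1)
})

test_that("constant outcome or predictor produces a structured skip", {
  fit <- fit_logistic_assoc(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_true(fit$skipped)
  expect_true(is.na(fit$beta))
  fit2 <- fit_logistic_assoc(rep(c(TRUE, FALSE), 5), rep(TRUE, 10))
  expect_true(fit2$skipped)
})

test_that("covariate-adjusted fit matches glm and survives separation", {
  set.seed(8)
  n <- 500
  x <- runif(n) < 0.4
  z <- rnorm(n)
  y <- runif(n) < plogis(-0.5 + 0.8 * x + 0.5 * z)
  fit <- fit_logistic_assoc(y, x, covariates = cbind(z = z))
  g <- glm(y ~ x + z, family = binomial())
  expect_equal(fit$beta, unname(coef(g)["xTRUE"]), tolerance = 1e-6)
  expect_false(fit$fallback)
  # perfect separation: outcome identical to predictor
  sep <- fit_logistic_assoc(x, x, covariates = cbind(z = z))
  expect_true(sep$fallback)
  expect_true(is.finite(sep$beta))
})

test_that("null association p-values are uniform", {
  set.seed(10)
  p <- replicate(400, {
    y <- runif(2000) < 0.3
    x <- runif(2000) < 0.5
    fit_logistic_assoc(y, x)$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("run_phewas fits one association per phecode per site", {
  set.seed(11)
  n <- 400
  ids <- seq_len(n)
  case <- ids <= 100
  site <- stats::setNames(rep(1:2, length.out = n), ids)
  pm <- matrix(runif(n * 3) < c(0.4, 0.2, 0.1), nrow = n,
               dimnames = list(ids, c("100.00", "200.00", "300.00")))
  matched <- list(case_ids = ids[case], control_ids = ids[!case])
  res <- run_phewas(matched, pm, site)
  expect_equal(nrow(res), 6)
  expect_setequal(unique(res$site), 1:2)
  # cross-check one cell against a direct fit
  sel <- names(site)[site == 1]
  direct <- fit_logistic_assoc(pm[sel, "100.00"], as.integer(sel) <= 100)
  got <- res[phenotype_id == "100.00" & site == 1]
  expect_equal(got$beta, direct$beta, tolerance = 1e-10)
  expect_equal(got$se, direct$se, tolerance = 1e-10)
  # a phecode perfectly tracking case status is flagged, not an error
  pm2 <- cbind(pm, "400.00" = case)
  res2 <- run_phewas(matched, pm2, site)
  expect_true(all(res2[phenotype_id == "400.00"]$fallback))
  # empty matrix: empty result
  expect_equal(nrow(run_phewas(matched, pm[, 0, drop = FALSE], site)), 0)
})
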