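test_that("partial correlation reduces to Pearson and matches the recursion oracle", {
  set.seed(31)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  expect_equal(partial_correlation(x, x)$r, 1)

  z <- rnorm(40)
  got <- partial_correlation(x, y, cbind(z = z))
  expect_equal(got$r, oracle_pcorr_1cov(x, y, z), tolerance = 1e-10)
  expect_equal(got$df, 40 - 2 - 1)
  # p value from the t transform
  tstat <- got$r * sqrt(got$df / (1 - got$r^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), got$df))

  # y (almost) fully explained by the covariates leaves r near 0
  Z <- cbind(a = rnorm(60), b = rnorm(60))
  y2 <- 2 * Z[, 1] - Z[, 2] + rnorm(60, sd = 1e-6)
  expect_lt(abs(partial_correlation(rnorm(60), y2, Z)$r), 0.5)
  # exactly explained: constant residuals are an error
  expect_error(partial_correlation(rnorm(60), 2 * Z[, 1] - Z[, 2], Z),
               "constant residuals")
})

test_that("partial correlation is invariant to affine transforms of the covariates and drops collinear columns", {
  set.seed(32)
  x <- rnorm(50); y <- rnorm(50)
  Z <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  A <- matrix(c(2, 0.5, 0, -1, 3, 0.2, 0.1, 0, 1), 3, 3)
  shifted <- Z %*% A + matrix(c(5, -2, 7), 50, 3, byrow = TRUE)
  expect_equal(partial_correlation(x, y, Z)$r,
               partial_correlation(x, y, shifted)$r, tolerance = 1e-10)
  expect_warning(res <- partial_correlation(x, y, cbind(Z, d = Z[, 1] * 2)),
                 "collinear")
  expect_equal(res$r, partial_correlation(x, y, Z)$r, tolerance = 1e-10)
})

test_that("the pooled t test matches hand arithmetic and its symmetries", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  got <- two_sample_t(a, b)
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 4)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(two_sample_t(b, a)$t, -got$t)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("the 2x2 chi-squared test matches direct (O-E)^2/E arithmetic", {
  prop <- matrix(c(10, 20, 10, 20), 2, 2)
  got <- chi_square_2x2(prop)
  expect_equal(got$statistic, 0)
  expect_equal(got$p, 1)

  tab <- matrix(c(20, 5, 5, 20), 2, 2)
  # direct Pearson arithmetic
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_2x2(tab)$statistic, sum((tab - E)^2 / E))
  expect_equal(chi_square_2x2(tab)$statistic, 18)
  expect_equal(chi_square_2x2(t(tab))$statistic, chi_square_2x2(tab)$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("stepwise regression selects the planted predictor and reduces to OLS at unit thresholds", {
  set.seed(33)
  exact <- 0L; planted <- 0L; R <- 60
  for (i in seq_len(R)) {
    X <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    y <- 0.4 * X[, 1] + rnorm(200)
    sel <- stepwise_regression(y, X)$selected
    if ("x1" %in% sel) planted <- planted + 1L
    if (identical(sel, "x1")) exact <- exact + 1L
  }
  expect_equal(planted, R)        # the real effect always enters
  expect_gt(exact / R, 0.5)       # and is usually the sole predictor

  # p_enter = p_remove = 1 retains everything and equals full OLS
  X <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X %*% c(0.5, -0.3, 0.2, 0) + rnorm(100)
  sw <- stepwise_regression(y, X, p_enter = 1, p_remove = 1)
  expect_setequal(sw$selected, colnames(X))
  full <- stats::lm(scale(y) ~ scale(X))
  expect_equal(unname(sw$betas[colnames(X)]), unname(coef(full)[-1]),
               tolerance = 1e-8)

  # near-orthogonal design with one overwhelming effect: standardized beta
  # matches the full-model least-squares beta
  Xo <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3))) * 10
  colnames(Xo) <- c("a", "b", "c")
  yo <- 5 * Xo[, 1] + rnorm(100, sd = 0.1)
  swo <- stepwise_regression(yo, Xo)
  expect_true("a" %in% swo$selected)
  fullo <- stats::lm(scale(yo) ~ scale(Xo))
  expect_equal(unname(swo$betas[["a"]]), unname(coef(fullo)[["scale(Xo)a"]]),
               tolerance = 1e-3)
})

test_that("stepwise null behaviour tracks the entry threshold", {
  set.seed(34)
  R <- 200
  entered <- 0L
  for (i in seq_len(R)) {
    X <- matrix(rnorm(57 * 5), 57, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- rnorm(57)
    if (length(stepwise_regression(y, X)$selected) > 0) entered <- entered + 1L
  }
  # P(any of 5 enters) ~ 1 - 0.95^5 = 0.226; binomial 4*SE band at R = 200
  expect_gt(entered / R, 0.226 - 4 * sqrt(0.226 * 0.774 / R))
  expect_lt(entered / R, 0.226 + 4 * sqrt(0.226 * 0.774 / R))
})

test_that("the cohort report is complete, deterministic, and tracks the planted structure", {
  co <- gen_cohort(cohort_params(seed = 35))
  rep1 <- run_cohort_analysis(co)
  rep2 <- run_cohort_analysis(co)
  expect_identical(rep1$correlations, rep2$correlations)
  expect_identical(rep1$stepwise$selected, rep2$stepwise$selected)
  expect_equal(nrow(rep1$correlations), 10)
  expect_true(all(c("cnr_lc", "cnr_sn", "age") %in%
                    rep1$group_comparison$variable))

  expect_error(run_cohort_analysis(co[, setdiff(names(co), "ledd")]),
               "ledd")

  # under a planted CNR_LC effect only, stepwise prefers CNR_LC over CNR_SN
  picks <- vapply(1:25, function(s) {
    rep <- run_cohort_analysis(gen_cohort(cohort_params(seed = 100 + s)))
    ("cnr_lc" %in% rep$stepwise$selected) &&
      !("cnr_sn" %in% rep$stepwise$selected)
  }, logical(1))
  expect_gt(mean(picks), 0.5)

  # global null: reported correlations stay small
  null_co <- gen_cohort(cohort_params(target_r = 0, target_r_sync = 0,
                                      covariate_effects = list(
                                        cnr_lc = c(age = 0, duration = 0, ledd = 0),
                                        cnr_sn = c(age = 0, duration = 0, ledd = 0),
                                        rate_updrs = c(age = 0, duration = 0, ledd = 0),
                                        rate_sync = c(age = 0, duration = 0, ledd = 0)),
                                      seed = 36))
  null_rep <- run_cohort_analysis(null_co)
  expect_lt(max(abs(null_rep$correlations$r)), 0.5)
})
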