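#' Partial correlation by double residualization
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and correlates the residuals — the construction whose
#' residuals are the quantities plotted in covariate-adjusted correlation
#' figures. The p value comes from the t statistic
#' \eqn{r\sqrt{df / (1 - r^2)}} on \eqn{df = n - 2 - p_{cov}}, two-sided.
#' With no covariates this reduces exactly to the Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional numeric matrix / data frame of covariates
#'   (e.g. age, duration of dopaminergic drug administration, LEDD);
#'   collinear columns are dropped with a warning.
#' @return An object of class `partial_corr`: `r`, `p`, `df`, `covariates`
#'   (retained names) and `residuals` (two-column matrix).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  Z <- NULL
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
    assert_that(nrow(Z) == n, "covariate rows must match x and y")
  }
  p_cov <- if (is.null(Z)) 0L else ncol(Z)
  assert_that(n > p_cov + 2L, "need n > number of covariates + 2")
  X <- cbind(intercept = rep(1, n), Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    warning(sprintf("dropping %d collinear covariate column(s)",
                    ncol(X) - qx$rank))
    X <- X[, keep, drop = FALSE]
    qx <- qr(X)
    p_cov <- ncol(X) - 1L
  }
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    stop("constant residuals: correlation undefined", call. = FALSE)
  }
  r <- cor(rx, ry)
  df <- n - 2L - p_cov
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  structure(list(r = r, p = p, df = df,
                 covariates = if (p_cov > 0) colnames(X)[-1] else character(0),
                 residuals = cbind(x = rx, y = ry)),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("<partial_corr> r = %.3f, p = %.4g, df = %d%s\n", x$r, x$p, x$df,
              if (length(x$covariates)) {
                paste0(" | ", paste(x$covariates, collapse = ", "))
              } else ""))
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return A list with `t`, `p` (two-sided) and `df`.
#' @export
two_sample_t <- function(a, b) {
  assert_that(length(a) >= 2L && length(b) >= 2L,
              "each group needs at least 2 observations")
  pooled_var <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled_var <= 0) stop("zero pooled variance: t undefined", call. = FALSE)
  fit <- t.test(a, b, var.equal = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction, df = 1; used for categorical group
#' comparisons such as gender.
#'
#' @param table 2x2 matrix of non-negative integer counts; all marginals
#'   must be positive.
#' @return A list with `statistic`, `p` and `df`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  assert_that(all(dim(table) == c(2L, 2L)), "table must be 2x2")
  assert_that(all(table >= 0) && all(abs(table - round(table)) < 1e-9),
              "table must hold non-negative integer counts")
  assert_that(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "a zero marginal makes the test undefined")
  fit <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Stepwise multiple linear regression with p-value criteria
#'
#' Forward selection with backward elimination in the convention of classic
#' statistical packages: at each step the candidate with the smallest
#' partial-F p value enters if it is at most `p_enter`; then any retained
#' predictor whose p value in the current model exceeds `p_remove` is
#' removed, worst first. Iteration stops at a fixed point. The final model
#' is refit on unit-variance response and predictors, so the reported
#' coefficients are standardized betas.
#'
#' @param y numeric response vector.
#' @param candidates named numeric matrix / data frame of candidate
#'   predictors.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @return An object of class `stepwise_result`: `selected` (ordered names),
#'   `betas` (standardized), `p_values`, and `steps` (data frame audit log
#'   of enter/remove events).
#' @export
stepwise_regression <- function(y, candidates, p_enter = 0.05,
                                p_remove = 0.10) {
  X <- as.matrix(candidates)
  assert_that(!is.null(colnames(X)) && !anyDuplicated(colnames(X)),
              "candidates must have unique column names")
  n <- length(y)
  assert_that(nrow(X) == n, "candidate rows must match y")
  assert_that(n > ncol(X) + 2L, "need n > number of candidates + 2")

  coef_p <- function(vars) {
    # p values of each coefficient (partial F = squared t) in y ~ vars
    fit <- stats::lm(y ~ ., data = as.data.frame(X[, vars, drop = FALSE]))
    cf <- summary(fit)$coefficients
    setNames(cf[-1, 4], vars)
  }

  model <- character(0)
  steps <- list()
  seen <- character(0)
  max_iter <- max(2L * ncol(X), 2L)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # forward: best candidate by partial-F p value
    pool <- setdiff(colnames(X), model)
    if (length(pool) > 0) {
      entry_p <- vapply(pool, function(v) coef_p(c(model, v))[[v]], numeric(1))
      best <- which.min(entry_p)
      if (entry_p[best] <= p_enter) {
        model <- c(model, pool[best])
        steps[[length(steps) + 1L]] <- data.frame(
          step = iter, action = "enter", variable = pool[best],
          p = unname(entry_p[best]))
        changed <- TRUE
      }
    }
    # backward: evict predictors above the removal threshold, worst first
    repeat {
      if (length(model) == 0) break
      pv <- coef_p(model)
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        steps[[length(steps) + 1L]] <- data.frame(
          step = iter, action = "remove", variable = model[worst],
          p = unname(pv[worst]))
        model <- model[-worst]
        changed <- TRUE
      } else break
    }
    sig <- paste(sort(model), collapse = "+")
    if (!changed) break
    if (sig %in% seen) {
      stop("stepwise selection cycled without converging", call. = FALSE)
    }
    seen <- c(seen, sig)
    if (iter == max_iter && length(setdiff(colnames(X), model)) > 0) {
      stop("stepwise selection did not converge within the iteration cap",
           call. = FALSE)
    }
  }

  if (length(model) > 0) {
    dstd <- as.data.frame(scale(X[, model, drop = FALSE]))
    fit <- stats::lm(scale(y) ~ ., data = dstd)
    cf <- summary(fit)$coefficients
    betas <- setNames(cf[-1, 1], model)
    pvals <- setNames(cf[-1, 4], model)
  } else {
    betas <- numeric(0)
    pvals <- numeric(0)
  }
  structure(list(selected = model, betas = betas, p_values = pvals,
                 steps = if (length(steps)) do.call(rbind, steps) else
                   data.frame(step = integer(0), action = character(0),
                              variable = character(0), p = numeric(0))),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (length(x$selected) == 0) {
    cat("<stepwise_result> empty model (no predictor met the entry criterion)\n")
  } else {
    cat("<stepwise_result> selected:",
        paste(sprintf("%s (beta = %.3f, p = %.3g)", x$selected, x$betas,
                      x$p_values), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the complete cohort analysis
#'
#' The inferential layer over a cohort table: rates of change and the
#' response/resistance split, per-variable group comparisons (pooled t
#' tests; chi-squared for sex when both levels are present), the
#' covariate-adjusted correlation set — imaging contrast against OFF/ON
#' UPDRS-III with age as covariate, and against the rates of change (and
#' the rates against each other) with age, medication duration and LEDD as
#' covariates — and the stepwise regression of the UPDRS-III rate of change
#' on CNR_LC, CNR_SN, age, duration and LEDD.
#'
#' @param cohort data frame with columns `age`, `duration_med`, `ledd`,
#'   `cnr_lc`, `cnr_sn`, `updrs3_off`, `updrs3_on`, `sync_off`, `sync_on`
#'   (and optionally `sex` coded 0/1).
#' @return An object of class `cohort_report`: the labeled cohort,
#'   `group_comparison`, `correlations`, `stepwise` and `n_tests`.
#' @export
run_cohort_analysis <- function(cohort) {
  need <- c("age", "duration_med", "ledd", "cnr_lc", "cnr_sn",
            "updrs3_off", "updrs3_on", "sync_off", "sync_on")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    stop("missing cohort columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  labeled <- split_by_response(cohort)
  resp <- labeled[labeled$group == "response", ]
  resi <- labeled[labeled$group == "resistance", ]

  cmp_vars <- c("age", "duration_med", "ledd", "updrs3_off", "cnr_lc", "cnr_sn")
  group_comparison <- do.call(rbind, lapply(cmp_vars, function(v) {
    tt <- two_sample_t(resp[[v]], resi[[v]])
    data.frame(variable = v, test = "t",
               response_mean = mean(resp[[v]]), resistance_mean = mean(resi[[v]]),
               statistic = tt$t, p = tt$p)
  }))
  if ("sex" %in% names(labeled) && length(unique(labeled$sex)) == 2L) {
    tab <- table(labeled$group, labeled$sex)
    cs <- chi_square_2x2(tab)
    group_comparison <- rbind(group_comparison, data.frame(
      variable = "sex", test = "chi-squared",
      response_mean = mean(resp$sex), resistance_mean = mean(resi$sex),
      statistic = cs$statistic, p = cs$p))
  }

  labeled$change_updrs <- original_change_updrs(labeled$updrs3_off,
                                                labeled$updrs3_on)
  age_only <- labeled[, "age", drop = FALSE]
  full_cov <- labeled[, c("age", "duration_med", "ledd")]
  pairs <- list(
    list("cnr_lc", "updrs3_off", age_only),
    list("cnr_lc", "updrs3_on", age_only),
    list("cnr_sn", "updrs3_off", age_only),
    list("cnr_sn", "updrs3_on", age_only),
    list("cnr_lc", "rate_updrs", full_cov),
    list("cnr_lc", "rate_sync", full_cov),
    list("cnr_sn", "rate_updrs", full_cov),
    list("cnr_sn", "rate_sync", full_cov),
    list("rate_updrs", "rate_sync", full_cov),
    list("cnr_lc", "change_updrs", full_cov))
  correlations <- do.call(rbind, lapply(pairs, function(pr) {
    pc <- partial_correlation(labeled[[pr[[1]]]], labeled[[pr[[2]]]], pr[[3]])
    data.frame(x = pr[[1]], y = pr[[2]],
               covariates = paste(colnames(pr[[3]]), collapse = "+"),
               r = pc$r, p = pc$p, df = pc$df)
  }))

  sw <- stepwise_regression(
    labeled$rate_updrs,
    labeled[, c("cnr_lc", "cnr_sn", "age", "duration_med", "ledd")])

  structure(list(cohort = labeled, group_comparison = group_comparison,
                 correlations = correlations, stepwise = sw,
                 n_tests = nrow(group_comparison) + nrow(correlations) + 1L),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d (response %d / resistance %d), %d tests run\n",
              nrow(x$cohort), sum(x$cohort$group == "response"),
              sum(x$cohort$group == "resistance"), x$n_tests))
  cat("\nGroup comparison:\n")
  print(x$group_comparison, row.names = FALSE, digits = 3)
  cat("\nCovariate-adjusted correlations:\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  cat("\nStepwise regression of the UPDRS-III rate of change:\n")
  print(x$stepwise)
  invisible(x)
}
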