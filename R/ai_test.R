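# The artificial-imputation (AI) conditional test: a 1-df likelihood-ratio
# test (binary trait) or F test (quantitative trait) of the anchor SNP given
# the partner SNP, with optional covariates. Genotype effects are always
# coded additively on the log-odds scale (multiplicative odds); dominant or
# recessive analysis codings lose power even under matching causal models and
# are deliberately not offered.

#' Maximum-likelihood logistic fit
#'
#' Fits a binomial logistic regression by iteratively reweighted least
#' squares. Thin wrapper over [stats::glm.fit()] returning the maximized
#' log-likelihood needed for likelihood-ratio tests. A fit with fitted
#' probabilities pinned at 0/1 (complete separation) is reported as
#' non-converged.
#'
#' @param y 0/1 response vector (no missing values).
#' @param X design matrix including an intercept column.
#' @return List with `coefficients`, `log_likelihood`, `converged`, `n_used`
#'   and `fitted`.
#' @export
fit_logistic <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    return(list(coefficients = rep(NA_real_, ncol(X)),
                log_likelihood = NA_real_, converged = FALSE,
                n_used = length(y), fitted = NULL, degenerate = TRUE))
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 50)))
  separated <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
  # deviance for ungrouped binary data: -2 * log-likelihood
  list(coefficients = fit$coefficients,
       log_likelihood = -fit$deviance / 2,
       converged = fit$converged && !fit$boundary && !separated,
       n_used = length(y), fitted = fit$fitted.values, degenerate = FALSE)
}

# Resolve covariates (covariate_table, matrix or NULL) into a numeric matrix
# aligned with n individuals plus a logical usability mask. Individuals
# flagged excluded in a covariate_table (absent from the covariate file) or
# with any missing covariate are unusable.
.covariate_design <- function(covariates, n) {
  if (is.null(covariates))
    return(list(C = matrix(numeric(0), nrow = n, ncol = 0),
                usable = rep(TRUE, n)))
  if (inherits(covariates, "covariate_table")) {
    C <- as.matrix(covariates$values)
    usable <- !covariates$excluded
  } else {
    C <- as.matrix(covariates)
    usable <- rep(TRUE, nrow(C))
  }
  stopifnot(nrow(C) == n)
  if (ncol(C) > 0) usable <- usable & stats::complete.cases(C)
  list(C = C, usable = usable)
}

.ai_result <- function(anchor_id, partner_id, statistic, df, p_value,
                       test_type, single_stat, single_p, status, n_used) {
  structure(list(anchor_id = anchor_id, partner_id = partner_id,
                 statistic = statistic, df = df, p_value = p_value,
                 test_type = test_type,
                 single_snp_statistic = single_stat,
                 single_snp_p = single_p,
                 status = status, n_used = n_used),
            class = "ai_test_result")
}

#' @export
print.ai_test_result <- function(x, ...) {
  cat("AI test (", x$test_type, "): ", x$anchor_id, " | ", x$partner_id,
      "\n", sep = "")
  cat("  status:", x$status, " n =", x$n_used, "\n")
  if (x$status == "ok") {
    cat("  AI statistic =", format(x$statistic, digits = 5),
        " p =", format(x$p_value, digits = 4), "\n")
    cat("  single-SNP statistic =", format(x$single_snp_statistic,
                                           digits = 5),
        " p =", format(x$single_snp_p, digits = 4), "\n")
  }
  invisible(x)
}

#' AI conditional test for a binary trait
#'
#' Likelihood-ratio test of the logistic model
#' `logit p = b0 + b1 * anchor + b2 * partner (+ covariates)` against the
#' nested model without the anchor term, on one degree of freedom. The
#' companion single-SNP logistic test of the anchor is computed on the same
#' individuals. Individuals missing the phenotype, either genotype, or any
#' covariate are dropped (complete-case per test).
#'
#' @param anchor,partner dosage vectors for the anchor and partner SNPs.
#' @param y binary phenotype (0 = control, 1 = case, NA missing).
#' @param covariates optional `covariate_table` or numeric matrix.
#' @param anchor_id,partner_id labels carried into the result.
#' @return An `ai_test_result` with fields `statistic`, `df = 1`, `p_value`,
#'   the companion single-SNP statistic and p-value, and a `status` of
#'   `"ok"`, `"degenerate"` or `"not_converged"`.
#' @export
ai_test_binary <- function(anchor, partner, y, covariates = NULL,
                           anchor_id = "anchor", partner_id = "partner") {
  cov <- .covariate_design(covariates, length(y))
  use <- !is.na(anchor) & !is.na(partner) & !is.na(y) & cov$usable
  n <- sum(use)
  a <- anchor[use]; p <- partner[use]; yy <- y[use]
  Cu <- cov$C[use, , drop = FALSE]

  sing <- single_snp_test(anchor, y, covariates, type = "binary")
  fail <- function(status)
    .ai_result(anchor_id, partner_id, NA_real_, 1L, NA_real_, "logistic_LRT",
               sing$statistic, sing$p_value, status, n)

  if (n < 4 || length(unique(yy)) < 2) return(fail("degenerate"))
  if (stats::var(a) == 0 || stats::var(p) == 0) return(fail("degenerate"))
  if (qr(cbind(1, a, p))$rank < 3) return(fail("degenerate"))

  X1 <- cbind(`(Intercept)` = 1, anchor = a, partner = p, Cu)
  X0 <- cbind(`(Intercept)` = 1, partner = p, Cu)
  f1 <- fit_logistic(yy, X1)
  f0 <- fit_logistic(yy, X0)
  if (!f1$converged || !f0$converged) return(fail("not_converged"))

  stat <- max(2 * (f1$log_likelihood - f0$log_likelihood), 0)
  .ai_result(anchor_id, partner_id, stat, 1L,
             pchisq(stat, df = 1, lower.tail = FALSE), "logistic_LRT",
             sing$statistic, sing$p_value, "ok", n)
}

#' AI conditional test for a quantitative trait
#'
#' Compares the linear models `y ~ anchor + partner (+ covariates)` and
#' `y ~ partner (+ covariates)` by the F statistic
#' `(RSS0 - RSS1) / (RSS1 / (n - 3 - c))` on `(1, n - 3 - c)` degrees of
#' freedom, where `c` is the number of covariates.
#'
#' @inheritParams ai_test_binary
#' @param y quantitative phenotype (NA missing).
#' @return An `ai_test_result` with `test_type = "linear_F"`.
#' @export
ai_test_quantitative <- function(anchor, partner, y, covariates = NULL,
                                 anchor_id = "anchor",
                                 partner_id = "partner") {
  cov <- .covariate_design(covariates, length(y))
  use <- !is.na(anchor) & !is.na(partner) & !is.na(y) & cov$usable
  n <- sum(use)
  a <- anchor[use]; p <- partner[use]; yy <- y[use]
  Cu <- cov$C[use, , drop = FALSE]
  cc <- ncol(Cu)

  sing <- single_snp_test(anchor, y, covariates, type = "quantitative")
  fail <- function(status)
    .ai_result(anchor_id, partner_id, NA_real_, 1L, NA_real_, "linear_F",
               sing$statistic, sing$p_value, status, n)

  df2 <- n - 3 - cc
  if (n < 4 || df2 < 1) return(fail("degenerate"))
  if (stats::var(yy) == 0 || stats::var(a) == 0 || stats::var(p) == 0)
    return(fail("degenerate"))
  if (qr(cbind(1, a, p))$rank < 3) return(fail("degenerate"))

  X1 <- cbind(1, a, p, Cu)
  X0 <- cbind(1, p, Cu)
  rss1 <- sum(lm.fit(X1, yy)$residuals^2)
  rss0 <- sum(lm.fit(X0, yy)$residuals^2)
  # the anchor explains nothing beyond rounding noise -> F = 0 exactly
  tss <- sum((yy - mean(yy))^2)
  if (rss0 - rss1 <= 1e-10 * tss) {
    Fstat <- 0
  } else {
    Fstat <- max((rss0 - rss1) / (rss1 / df2), 0)
  }
  .ai_result(anchor_id, partner_id, Fstat, 1L,
             pf(Fstat, 1, df2, lower.tail = FALSE), "linear_F",
             sing$statistic, sing$p_value, "ok", n)
}

#' Single-SNP association test
#'
#' One-degree-of-freedom test of a SNP term against the covariate-only null:
#' a logistic likelihood-ratio test for a binary phenotype (values in
#' `{0, 1}`) or an F test for a quantitative phenotype.
#'
#' @param g dosage vector.
#' @param y phenotype vector.
#' @param covariates optional `covariate_table` or numeric matrix.
#' @param type phenotype type; `"auto"` treats a 0/1-valued `y` as binary.
#' @return List with `statistic`, `p_value`, `df`, `status` and `n_used`.
#' @export
single_snp_test <- function(g, y, covariates = NULL,
                            type = c("auto", "binary", "quantitative")) {
  type <- match.arg(type)
  cov <- .covariate_design(covariates, length(y))
  use <- !is.na(g) & !is.na(y) & cov$usable
  n <- sum(use)
  gg <- g[use]; yy <- y[use]
  Cu <- cov$C[use, , drop = FALSE]
  cc <- ncol(Cu)
  fail <- function(status) list(statistic = NA_real_, p_value = NA_real_,
                                df = NA, status = status, n_used = n)
  if (n < 3 || stats::var(gg) == 0) return(fail("degenerate"))

  binary <- switch(type, binary = TRUE, quantitative = FALSE,
                   auto = all(yy %in% c(0, 1)))
  if (binary) {
    if (length(unique(yy)) < 2) return(fail("degenerate"))
    f1 <- fit_logistic(yy, cbind(1, gg, Cu))
    f0 <- fit_logistic(yy, cbind(1, Cu))
    if (!f1$converged || !f0$converged) return(fail("not_converged"))
    stat <- max(2 * (f1$log_likelihood - f0$log_likelihood), 0)
    list(statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         df = 1, status = "ok", n_used = n)
  } else {
    df2 <- n - 2 - cc
    if (df2 < 1 || stats::var(yy) == 0) return(fail("degenerate"))
    rss1 <- sum(lm.fit(cbind(1, gg, Cu), yy)$residuals^2)
    rss0 <- sum(lm.fit(cbind(1, Cu), yy)$residuals^2)
    stat <- max((rss0 - rss1) / (rss1 / df2), 0)
    list(statistic = stat,
         p_value = pf(stat, 1, df2, lower.tail = FALSE),
         df = c(1, df2), status = "ok", n_used = n)
  }
}
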