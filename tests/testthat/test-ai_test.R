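# Logistic/linear fits, the AI conditional statistic and its companion
# single-SNP test, checked against independent optimizer / normal-equations
# oracles.

test_that("intercept-only logistic fit has the closed-form likelihood", {
  y <- rep(c(0, 1), each = 30)
  f <- fit_logistic(y, matrix(1, 60, 1))
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  expect_equal(f$log_likelihood, 60 * log(0.5), tolerance = 1e-10)
  expect_true(f$converged)
})

test_that("logistic fits agree with a numerical-optimizer oracle", {
  set.seed(101)
  for (rep in 1:25) {
    d <- random_cc_data(n = 100)
    X <- cbind(1, d$anchor, d$partner)
    f <- fit_logistic(d$y, X)
    expect_true(f$converged)
    expect_equal(f$log_likelihood, oracle_logistic_ll(d$y, X),
                 tolerance = 1e-6)
  }
})

test_that("perfect separation is reported as non-convergence", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(rep(0, 10), rep(2, 10))
  f <- fit_logistic(y, cbind(1, x))
  expect_false(f$converged)
})

test_that("AI statistic vanishes when genotypes carry no case/control signal", {
  # identical joint genotype distribution in cases and controls:
  # constant case:control ratio in every (x1, x2) cell
  cells <- expand.grid(x1 = 0:2, x2 = 0:2)
  counts <- c(30, 12, 4, 18, 20, 6, 3, 8, 9)
  x1 <- rep(rep(cells$x1, counts), 2)
  x2 <- rep(rep(cells$x2, counts), 2)
  y <- rep(c(0, 1), each = sum(counts))
  res <- ai_test_binary(x1, x2, y)
  expect_equal(res$statistic, 0, tolerance = 1e-6)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
  expect_equal(res$single_snp_statistic, 0, tolerance = 1e-6)
})

test_that("binary AI statistic equals twice the oracle log-likelihood gap", {
  set.seed(102)
  for (rep in 1:10) {
    d <- random_cc_data(n = 60)
    res <- ai_test_binary(d$anchor, d$partner, d$y)
    if (res$status != "ok") next
    ll1 <- oracle_logistic_ll(d$y, cbind(1, d$anchor, d$partner))
    ll0 <- oracle_logistic_ll(d$y, cbind(1, d$partner))
    expect_equal(res$statistic, max(2 * (ll1 - ll0), 0), tolerance = 1e-6)
  }
})

test_that("covariates shift the AI statistic without breaking the nesting", {
  set.seed(103)
  d <- random_cc_data(n = 200)
  C <- cbind(pc1 = rnorm(200), pc2 = rnorm(200))
  res <- ai_test_binary(d$anchor, d$partner, d$y, covariates = C)
  expect_identical(res$status, "ok")
  expect_gte(res$statistic, 0)
  ll1 <- oracle_logistic_ll(d$y, cbind(1, d$anchor, d$partner, C))
  ll0 <- oracle_logistic_ll(d$y, cbind(1, d$partner, C))
  expect_equal(res$statistic, max(2 * (ll1 - ll0), 0), tolerance = 1e-6)
})

test_that("quantitative F matches closed-form least squares", {
  set.seed(104)
  n <- 8
  a <- c(0, 1, 2, 1, 0, 2, 1, 0)
  p <- c(0, 0, 1, 2, 1, 1, 0, 2)
  y <- 1.3 + 0.4 * a - 0.7 * p + c(0.05, -0.1, 0.2, 0, -0.15, 0.1, -0.05, 0.08)
  res <- ai_test_quantitative(a, p, y)
  rss1 <- oracle_rss(y, cbind(1, a, p))
  rss0 <- oracle_rss(y, cbind(1, p))
  Fexp <- (rss0 - rss1) / (rss1 / (n - 3))
  expect_equal(res$statistic, Fexp, tolerance = 1e-8)
  expect_equal(res$p_value, pf(Fexp, 1, n - 3, lower.tail = FALSE),
               tolerance = 1e-8)

  # y exactly linear in the partner alone -> F = 0, p = 1
  y0 <- 2 - 0.5 * p
  res0 <- ai_test_quantitative(a, p, y0)
  expect_equal(res0$statistic, 0, tolerance = 1e-8)
  expect_equal(res0$p_value, 1)

  # permutation invariance
  ord <- sample(n)
  resp <- ai_test_quantitative(a[ord], p[ord], y[ord])
  expect_equal(resp$statistic, res$statistic, tolerance = 1e-10)
})

test_that("degenerate inputs are flagged rather than tested", {
  y <- rep(c(0, 1), 20)
  a <- rbinom(40, 2, 0.4)
  expect_identical(ai_test_binary(a, rep(1, 40), y)$status, "degenerate")
  expect_identical(ai_test_binary(a, a, y)$status, "degenerate")
  expect_identical(single_snp_test(rep(2, 40), y)$status, "degenerate")
  expect_identical(ai_test_binary(a, rbinom(40, 2, 0.5),
                                  rep(1, 40))$status, "degenerate")
})

test_that("missing phenotype/genotype/covariate rows are dropped per test", {
  set.seed(105)
  d <- random_cc_data(n = 150)
  a <- d$anchor; p <- d$partner; y <- d$y
  a[1:5] <- NA; p[6:8] <- NA; y[9:10] <- NA
  C <- cbind(pc = rnorm(150)); C[11, 1] <- NA
  res <- ai_test_binary(a, p, y, covariates = C)
  expect_equal(res$n_used, 150 - 11)
  use <- complete.cases(a, p, y, C)
  ll1 <- oracle_logistic_ll(y[use], cbind(1, a, p, C)[use, ])
  ll0 <- oracle_logistic_ll(y[use], cbind(1, p, C)[use, ])
  expect_equal(res$statistic, max(2 * (ll1 - ll0), 0), tolerance = 1e-6)
})

test_that("single-SNP test is calibrated and matches its oracle", {
  set.seed(106)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  y <- rep(c(0, 1), n / 2)
  res <- single_snp_test(g, y)
  ll1 <- oracle_logistic_ll(y, cbind(1, g))
  expect_equal(res$statistic, max(2 * (ll1 - n * log(0.5)), 0),
               tolerance = 1e-6)
  expect_lt(res$statistic, qchisq(0.999, 1))
})
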