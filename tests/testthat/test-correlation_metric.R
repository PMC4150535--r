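# Genotype/haplotype correlation, the partition sampler, case/control
# simulation, and metric-curve construction.

test_that("genotype r2 matches the direct Pearson formula and handles NAs", {
  expect_equal(genotype_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_true(is.na(genotype_r2(c(0, 1, 2, 1), c(1, 1, 1, 1))))
  g1 <- c(0, 0, 1, 1, 2, 2)
  g2 <- c(0, 1, 0, 1, 2, 2)
  expect_equal(genotype_r2(g1, g2), cor(g1, g2)^2)
  # pairwise-complete: the NA pair is dropped from both vectors
  expect_equal(genotype_r2(c(g1, 2), c(g2, NA)), cor(g1, g2)^2)
  expect_true(is.na(genotype_r2(c(0, NA), c(NA, 1))))
  expect_error(genotype_r2(c(0, 1), c(0, 1, 2)), "length")
})

test_that("haplotype-count r2 reproduces the published tagging correlations", {
  t1 <- table1_fixture()
  comb <- t1$case_count + t1$control_count
  combo <- t1$partner + t1$anchor
  expect_equal(haplotype_r2_from_counts(comb, t1$causal, t1$anchor),
               0.199, tolerance = 0.006 / 0.199)
  expect_equal(haplotype_r2_from_counts(t1$control_count, t1$causal,
                                        t1$anchor),
               0.255, tolerance = 0.006 / 0.255)
  expect_equal(haplotype_r2_from_counts(comb, t1$causal, combo),
               0.374, tolerance = 0.006 / 0.374)
  expect_equal(haplotype_r2_from_counts(t1$control_count, t1$causal, combo),
               0.438, tolerance = 0.006 / 0.438)
  # near-zero partner correlations, absolute bands
  expect_lt(abs(haplotype_r2_from_counts(t1$control_count, t1$causal,
                                         t1$partner) - 0.004), 0.003)
  expect_lt(abs(haplotype_r2_from_counts(comb, t1$causal, t1$partner) -
                  0.002), 0.006)
  expect_true(is.na(haplotype_r2_from_counts(c(1, 1), c(1, 1), c(0, 1))))
})

test_that("partition sampler is a valid exchangeable stick-breaking scheme", {
  set.seed(31)
  p <- sample_haplotype_partition(2e4)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  # exchangeability of the random pick order: each haplotype's marginal
  # mean frequency is 1/8
  expect_equal(unname(colMeans(p)), rep(1 / 8, 8), tolerance = 0.04)
  # distributional cross-check against an independent re-implementation of
  # the sequential-uniform scheme (first draw uniform on [0, 1], later draws
  # uniform on the remainder, random order)
  set.seed(32)
  oracle <- t(replicate(2e4, {
    f <- numeric(8)
    order <- sample(8)
    S <- 0
    for (k in 1:7) {
      u <- runif(1, 0, 1 - S)
      f[order[k]] <- u
      S <- S + u
    }
    f[order[8]] <- 1 - S
    f
  }))
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_lt(max(abs(quantile(as.vector(p), qs) -
                      quantile(as.vector(oracle), qs))), 0.01)
})

test_that("case/control simulation matches the analytic conditional law", {
  set.seed(21)
  fr <- c(0.30, 0.05, 0.10, 0.05, 0.20, 0.05, 0.10, 0.15)
  model <- haplotype_disease_model(fr, c(0.01, 0.015, 0.0225))
  sim <- simulate_case_control(model, 4000, 4000)
  expect_equal(dim(sim$genotypes), c(8000, 3))
  expect_equal(sum(sim$phenotype), 4000)

  # analytic case distribution of causal dosage: freq x penetrance renorm
  hap_d <- c(0, 0, 1, 1, 0, 0, 1, 1)  # causal bit of haplotype index
  qd <- sum(fr * hap_d)
  pg <- dbinom(0:2, 2, qd)
  pen <- c(0.01, 0.015, 0.0225)
  pcase <- pg * pen / sum(pg * pen)
  obs <- tabulate(sim$genotypes[sim$phenotype == 1, "causal"] + 1, 3) / 4000
  expect_equal(obs, pcase, tolerance = 0.05)

  # equal penetrances: disease independent of genotype
  m0 <- haplotype_disease_model(fr, c(0.01, 0.01, 0.01))
  s0 <- simulate_case_control(m0, 4000, 4000)
  fcase <- mean(s0$genotypes[s0$phenotype == 1, "causal"]) / 2
  fctrl <- mean(s0$genotypes[s0$phenotype == 0, "causal"]) / 2
  expect_equal(fcase, fctrl, tolerance = 0.05)
})

test_that("constructed metric curves are anchored, scaled and reproducible", {
  cfg <- metric_construction_config(n_replicates = 2e4, seed = 91)
  cv <- run_metric_construction(cfg, "multiplicative")
  grid <- seq(0, 1, by = 1e-3)
  sc <- score(cv, grid)
  expect_equal(score(cv, 0), 0)
  expect_equal(score(cv, 1), 0)
  expect_true(all(sc >= 0 & sc <= 100))
  expect_equal(max(sc), 100, tolerance = 1e-8)
  # bit-reproducible under the same seed
  cv2 <- run_metric_construction(cfg, "multiplicative")
  expect_identical(cv$q_coef, cv2$q_coef)
  expect_identical(cv$scale, cv2$scale)
  # undefined correlation scores zero
  expect_equal(score(cv, NA), 0)
})

test_that("lowering the top fraction does not move the peak upward", {
  cfg1 <- metric_construction_config(n_replicates = 1e5, seed = 55)
  cv1 <- run_metric_construction(cfg1, "multiplicative")
  cfg2 <- metric_construction_config(n_replicates = 1e5, top_fraction = 0.002,
                                     seed = 55)
  cv2 <- run_metric_construction(cfg2, "multiplicative")
  # non-increase within one bin width of resolution
  expect_lte(curve_argmax(cv2), curve_argmax(cv1) + 0.05)
})

test_that("metric curves survive JSON serialization", {
  cfg <- metric_construction_config(n_replicates = 5e3, seed = 8)
  cv <- run_metric_construction(cfg, "multiplicative")
  path <- file.path(withr::local_tempdir(), "curve.json")
  write_metric_curve(cv, path)
  back <- read_metric_curve(path)
  r2 <- seq(0, 1, by = 0.01)
  expect_equal(score(back, r2), score(cv, r2), tolerance = 1e-12)
  expect_identical(back$model, cv$model)
})
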