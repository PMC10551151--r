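test_that("posterior subsampling is uniform without replacement and seeded", {
  pool <- rnorm(500)
  set.seed(1)
  full <- subsample_posterior(pool, n = 500)
  expect_setequal(full, pool)            # a permutation of everything
  set.seed(2); a <- subsample_posterior(pool, n = 50)
  set.seed(2); b <- subsample_posterior(pool, n = 50)
  expect_identical(a, b)
  expect_error(subsample_posterior(pool, n = 501), "exceeds")
  # sampling-distribution oracle: subsample means stay within the
  # finite-population 3-sigma band around the pooled mean
  set.seed(3)
  pool2 <- rnorm(10000, mean = 20, sd = 2)
  se <- sd(pool2) / sqrt(50)
  hits <- replicate(10000, {
    abs(mean(pool2[sample.int(10000, 50)]) - mean(pool2)) < 3 * se
  })
  expect_gt(mean(hits), 0.99)
})

test_that("one-way ANOVA matches the hand-computed F and its invariances", {
  # identical groups: no between-group variance
  r0 <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0$f, 0)
  expect_equal(r0$p, 1)
  # hand oracle: SSB/SSW for {1,2,3} vs {4,5,6}
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  grand <- mean(c(g1, g2))
  ssb <- 3 * (mean(g1) - grand)^2 + 3 * (mean(g2) - grand)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  r <- anova_oneway(list(g1, g2))
  expect_equal(r$f, f_oracle, tolerance = 1e-12)
  expect_equal(r$f, 13.5, tolerance = 1e-12)
  expect_equal(r$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$df, c(1, 4))
  # translation invariance
  r_shift <- anova_oneway(list(g1 + 100, g2 + 100))
  expect_equal(r_shift$f, r$f, tolerance = 1e-10)
  # zero within-group variance with separated means is degenerate
  rd <- anova_oneway(list(c(1, 1), c(2, 2)))
  expect_true(rd$degenerate)
  expect_equal(rd$f, Inf)
  expect_equal(rd$p, 0)
  expect_error(anova_oneway(list(c(1, 2))), "2 groups")
  expect_error(anova_oneway(list(c(1, 2), 3)), "at least 2 values")
})

test_that("Tukey HSD produces all pairs with calibrated flags", {
  same <- list(a = c(1, 2, 3), b = c(1.1, 2, 2.9), c = c(0.9, 2, 3.1))
  tk <- tukey_hsd(same)
  expect_equal(nrow(tk), choose(3, 2))
  expect_false(any(tk$significant))
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
  # far-separated tight groups must flag
  set.seed(4)
  far <- list(lo = rnorm(50, 0, 1), hi = rnorm(50, 100, 1))
  tk2 <- tukey_hsd(far)
  expect_equal(nrow(tk2), 1)
  expect_true(tk2$significant)
  expect_lt(tk2$p_adj, 1e-6)
  # studentized-range oracle for the two-group case: Tukey p equals ptukey
  y <- unlist(far); g <- factor(rep(names(far), each = 50))
  fit <- aov(y ~ g)
  mse <- sum(fit$residuals^2) / fit$df.residual
  qstat <- unname(abs(diff(vapply(far, mean, 0)))) / sqrt(mse / 50)
  expect_equal(tk2$p_adj,
               ptukey(qstat, nmeans = 2, df = 98, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("identical-truth posteriors are rarely flagged; separated ones always", {
  # null side, aggregated over seeded replicates for robustness
  flags <- vapply(1:40, function(i) {
    set.seed(100 + i)
    pool <- rnorm(3000, 20, 1)
    res <- compare_parameters(list(a = pool, b = pool), factor_name = "method")
    res$anova$p < 0.05
  }, logical(1))
  expect_lt(mean(flags), 0.2)
  # a 3-posterior-sd shift is essentially always detected
  set.seed(5)
  res <- compare_parameters(list(a = rnorm(3000, 20, 1),
                                 b = rnorm(3000, 23, 1)),
                            factor_name = "environment")
  expect_lt(res$anova$p, 0.001)
  expect_true(all(res$tukey$significant))
  expect_equal(res$n, 50)
  expect_match(res$note, "unorthodox|descriptive")
  # determinism under a fixed seed
  set.seed(6); r1 <- compare_parameters(list(a = rnorm(100), b = rnorm(100)))
  set.seed(6); r2 <- compare_parameters(list(a = rnorm(100), b = rnorm(100)))
  expect_identical(r1$anova, r2$anova)
  expect_identical(r1$tukey, r2$tukey)
})

test_that("comparison works directly on fitted posterior draws", {
  sim <- simulate_dataset(tiny_field_config(seed = 51))
  fit <- fit_lrc(sim$data, config = fit_config(n_chains = 2, n_adapt = 300,
                                               n_iter = 100, thin = 1,
                                               seed = 3))
  set.seed(7)
  res <- compare_parameters(list(g1 = fit, g2 = fit),
                            parameter = c("mu_a_max[G1]", "mu_a_max[G2]"),
                            factor_name = "genotype", n = 40)
  expect_s3_class(res, "lrc_comparison")
  expect_equal(nrow(res$tukey), 1)
  expect_true(is.finite(res$anova$f))
})
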