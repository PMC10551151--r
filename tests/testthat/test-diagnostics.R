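test_that("PSRF follows the Gelman-Rubin formula on hand-checkable chains", {
  # identical chains: B = 0, PSRF = sqrt((n-1)/n) < 1
  r <- bgr_diagnostic(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$psrf, sqrt(2 / 3), tolerance = 1e-12)
  expect_false(r$degenerate)
  expect_true(attr(r, "converged"))
  r4 <- bgr_diagnostic(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(r4$psrf, sqrt(3 / 4), tolerance = 1e-12)
  # constant chains with different values: W = 0, degenerate not failed
  rd <- bgr_diagnostic(cbind(rep(0, 4), rep(10, 4)))
  expect_true(rd$degenerate)
  expect_true(attr(rd, "converged"))
  # a single chain is rejected
  expect_error(bgr_diagnostic(matrix(1:5, ncol = 1)), "2 chains")
  # far-separated chains flag non-convergence
  rs <- bgr_diagnostic(cbind(rnorm(100), rnorm(100) + 50))
  expect_gt(rs$psrf, 1.1)
  expect_false(attr(rs, "converged"))
})

test_that("PSRF approaches 1 with increasing draws from the target", {
  psrf_at <- function(n, seed) {
    set.seed(seed)
    bgr_diagnostic(cbind(rnorm(n), rnorm(n), rnorm(n)))$psrf
  }
  p <- c(psrf_at(50, 1), psrf_at(500, 1), psrf_at(5000, 1))
  expect_true(all(diff(abs(p - 1)) < 0))
  expect_lt(abs(p[3] - 1), 0.01)
})

test_that("thinning keeps every k-th draw and reduces autocorrelation", {
  x <- draws_from_series(seq_len(100))
  expect_identical(thin_draws(x, 1)$draws, x$draws)
  t10 <- thin_draws(x, 10)
  expect_equal(dim(t10$draws)[2], 10)
  expect_equal(unname(t10$draws[1, , 1]), seq(1, 91, by = 10))
  expect_error(thin_draws(x, 101), "exceeds")
  # AR(1) oracle: thinned lag-1 autocorrelation ~ rho^k < rho
  set.seed(42)
  n <- 20000; rho <- 0.9
  ar <- as.vector(stats::filter(rnorm(n), rho, method = "recursive"))
  d <- draws_from_series(ar)
  ac_raw <- stats::acf(ar, plot = FALSE, lag.max = 1)$acf[2]
  thinned <- thin_draws(d, 5)$draws[1, , 1]
  ac_thin <- stats::acf(thinned, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(ac_thin, ac_raw)
  expect_lt(abs(ac_raw - rho), 0.05)
  expect_lt(abs(ac_thin - rho^5), 0.1)
})

test_that("posterior predictive collapses to the curve for degenerate draws", {
  sim <- simulate_dataset(tiny_ladder_config(seed = 31))
  st <- sim$truth
  st$obs_precision <- 1e12  # essentially noise-free predictive
  d <- draws_from_state(st, n_chains = 2, n_iter = 10)
  set.seed(1)
  ppd <- posterior_predictive(d, sim$data)
  pp <- st$plant_params[sim$data$plant, ]
  mu <- nrh_mean_vecparams(pp, sim$data$PARi)
  expect_lt(max(abs(ppd$mean - mu)), 1e-4)
  expect_lt(max(ppd$upper - ppd$lower), 1e-4)
  expect_true(all(ppd$lower <= ppd$mean & ppd$mean <= ppd$upper))
  # label mismatch raises
  bad <- sim$data; bad$plant[1] <- "nope"; bad$genotype[1] <- "X"
  expect_error(posterior_predictive(d, bad), "without posterior draws")
})

test_that("predictive intervals from the generating state cover ~95% of data", {
  cfg <- sim_config(n_genotypes = 2, n_replicates = 2,
                    design = design_nonsequential(n_measurements = 250),
                    noise_sd = 1.0, seed = 33)
  sim <- simulate_dataset(cfg)       # 1000 observations
  d <- draws_from_state(sim$truth, n_chains = 2, n_iter = 1000)
  # identical states: predictive randomness comes from the likelihood draw
  set.seed(2)
  ppd <- posterior_predictive(d, sim$data)
  inside <- mean(sim$data$A >= ppd$lower & sim$data$A <= ppd$upper)
  expect_gt(inside, 0.92)
  expect_lt(inside, 0.98)
})

test_that("goodness of fit returns OLS slope/intercept and squared Pearson R", {
  obs <- c(1, 2, 3)
  g <- goodness_of_fit(obs, c(1, 2, 3))
  expect_equal(g$r_squared, 1)
  expect_equal(g$slope, 1)
  expect_equal(g$intercept, 0, tolerance = 1e-12)
  pred <- c(1.1, 1.9, 3.2)
  g2 <- goodness_of_fit(obs, pred)
  # independent Pearson oracle from the product-moment formula
  r_oracle <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(g2$r_squared, r_oracle^2, tolerance = 1e-12)
  expect_equal(round(g2$r_squared, 3), 0.981)
  # anti-correlation: R^2 is signless, the slope carries direction
  g3 <- goodness_of_fit(obs, c(3, 2, 1))
  expect_equal(g3$r_squared, 1)
  expect_equal(g3$slope, -1)
  expect_error(goodness_of_fit(obs, c(2, 2, 2)), "variance")
  expect_error(goodness_of_fit(obs, c(1, 2)), "length")
})
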