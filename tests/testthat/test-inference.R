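make_state <- function(sim) sim$truth

test_that("log likelihood matches direct normal-density summation", {
  pp <- matrix(c(20, 0.05, 1.5, 0.8), 1, 4,
               dimnames = list("G1.P1",
                               c("a_max", "alpha", "r_d", "theta")))
  gm <- matrix(c(20, 0.05, 1.5, 0.8), 1, 4,
               dimnames = list("G1", c("a_max", "alpha", "r_d", "theta")))
  st <- lrc_state(pp, gm, c(a_max = 1, alpha = 1, r_d = 1, theta = 1), 1)
  mu400 <- nrh_mean(lrc_params(20, 0.05, 1.5, 0.8), 400)
  d1 <- data.frame(genotype = "G1", plant = "G1.P1", PARi = 400, A = mu400)
  # one observation exactly at the mean, tau = 1: standard normal at zero
  expect_equal(log_likelihood(st, d1), log(1 / sqrt(2 * pi)), tolerance = 1e-10)
  expect_equal(log_likelihood(st, d1), -0.9189385, tolerance = 1e-6)
  # additivity: the dataset duplicated doubles the log density
  d2 <- rbind(d1, d1); d2$obs_id <- 1:2
  expect_equal(log_likelihood(st, d2), 2 * log_likelihood(st, d1),
               tolerance = 1e-12)
  # printed observations against an independent summation oracle
  d3 <- data.frame(genotype = "G1", plant = "G1.P1",
                   PARi = c(50, 400, 1500), A = c(0.7, 16.2, 18.9))
  st$obs_precision <- 4
  oracle <- sum(dnorm(d3$A,
                      sapply(d3$PARi, function(I)
                        nrh_mean(lrc_params(20, 0.05, 1.5, 0.8), I)),
                      sd = 1 / sqrt(4), log = TRUE))
  expect_equal(log_likelihood(st, d3), oracle, tolerance = 1e-10)
  # unknown plant raises
  d4 <- d1; d4$plant <- "G1.P9"
  expect_error(log_likelihood(st, d4), "without parameters")
})

test_that("log prior equals the per-term analytic sum and rejects truncation violations", {
  pr <- prior_spec()
  kn <- c("a_max", "alpha", "r_d", "theta")
  gm <- matrix(rep(pr$mean, each = 2), 2, 4,
               dimnames = list(c("G1", "G2"), kn))
  pp <- gm[c(1, 1, 2, 2), ]
  rownames(pp) <- c("G1.P1", "G1.P2", "G2.P1", "G2.P2")
  tg <- c(a_max = 1 / 1.5^2, alpha = 1 / 0.0025^2, r_d = 1 / 0.15^2,
          theta = 1 / 0.025^2)
  st <- lrc_state(pp, gm, tg, 1)
  # independent per-term oracle assembled from dnorm/pnorm/dgamma
  oracle <- 0
  for (k in kn) {
    sdk <- 1 / sqrt(tg[[k]])
    zk <- pnorm(pr$upper[[k]], gm[1, k], sdk) - pnorm(pr$lower[[k]], gm[1, k], sdk)
    oracle <- oracle + 4 * (dnorm(pp[1, k], gm[1, k], sdk, log = TRUE) - log(zk))
    z0 <- pnorm(pr$upper[[k]], pr$mean[[k]], pr$sd[[k]]) -
      pnorm(pr$lower[[k]], pr$mean[[k]], pr$sd[[k]])
    oracle <- oracle + 2 * (dnorm(gm[1, k], pr$mean[[k]], pr$sd[[k]],
                                  log = TRUE) - log(z0))
    oracle <- oracle + dgamma(tg[[k]], 0.01, 0.01, log = TRUE)
  }
  oracle <- oracle + dgamma(1, 0.01, 0.01, log = TRUE)
  expect_equal(log_prior(st, pr), oracle, tolerance = 1e-10)

  # a plant theta beyond its truncation bound scores -Inf
  bad <- unclass(st)
  bad$plant_params["G1.P1", "theta"] <- 1.2
  expect_identical(log_prior(bad, pr), -Inf)
})

test_that("tightening a genotype precision penalises off-mean plants (finite difference)", {
  pr <- prior_spec()
  kn <- c("a_max", "alpha", "r_d", "theta")
  gm <- matrix(pr$mean, 1, 4, dimnames = list("G1", kn))
  tau1 <- 1 / 1.5^2
  pp <- gm[rep(1, 3), ]
  pp[, "a_max"] <- pr$mean[["a_max"]] + 3 * 1.5   # 3 sd off the genotype mean
  rownames(pp) <- paste0("G1.P", 1:3)
  tg1 <- c(a_max = tau1, alpha = 1e4, r_d = 10, theta = 100)
  tg2 <- tg1; tg2["a_max"] <- tau1 * 1.1
  lp_off_1 <- log_prior(lrc_state(pp, gm, tg1, 1), pr)
  lp_off_2 <- log_prior(lrc_state(pp, gm, tg2, 1), pr)
  pp_on <- pp; pp_on[, "a_max"] <- pr$mean[["a_max"]]
  lp_on_1 <- log_prior(lrc_state(pp_on, gm, tg1, 1), pr)
  lp_on_2 <- log_prior(lrc_state(pp_on, gm, tg2, 1), pr)
  # off-mean: density loss beats the normalisation gain, so lp decreases
  expect_lt(lp_off_2 - lp_off_1, 0)
  # the decrease is specific to the deviation: at the mean the same precision
  # change helps
  expect_gt(lp_on_2 - lp_on_1, 0)
})

test_that("sampler configuration contracts hold", {
  expect_error(fit_config(n_chains = 1), "n_chains")
  expect_error(fit_config(n_iter = 0), "n_iter")
  expect_error(fit_config(thin = 0), "thin")
  expect_error(fit_config(fixed = list(bogus = 1)), "bogus")
  sim <- simulate_dataset(tiny_field_config(seed = 21))
  expect_error(fit_lrc(sim$data[0, ], config = fit_config(n_chains = 2,
                                                          n_iter = 10,
                                                          thin = 1)),
               "empty|mandatory")
})

test_that("fit returns the configured draw counts and respects all truncations", {
  sim <- simulate_dataset(tiny_field_config(seed = 22))
  cfg <- fit_config(n_chains = 2, n_adapt = 400, n_iter = 80, thin = 2,
                    seed = 5)
  fit <- fit_lrc(sim$data, config = cfg)
  expect_s3_class(fit, "lrc_draws")
  expect_equal(dim(fit$draws), c(2, 80, length(fit$par_names)))
  pm <- posterior_matrix(fit)
  expect_equal(nrow(pm), 160)
  b <- param_bounds()
  for (k in c("a_max", "alpha", "r_d", "theta")) {
    cols <- grep(paste0("^(mu_)?", k, "\\["), fit$par_names, value = TRUE)
    vals <- pm[, cols]
    expect_true(all(vals > b$lower[[k]] & vals <= b$upper[[k]]))
  }
  expect_true(all(pm[, grep("^tau", fit$par_names)] > 0))
})

test_that("fitting is deterministic given the seed", {
  sim <- simulate_dataset(tiny_field_config(seed = 23))
  cfg <- fit_config(n_chains = 2, n_adapt = 300, n_iter = 50, thin = 1,
                    seed = 9)
  f1 <- fit_lrc(sim$data, config = cfg)
  f2 <- fit_lrc(sim$data, config = cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("relabelling genotypes permutes the genotype-level posterior", {
  sim <- simulate_dataset(tiny_field_config(seed = 24))
  cfg <- fit_config(n_chains = 2, n_adapt = 300, n_iter = 50, thin = 1,
                    seed = 13)
  f1 <- fit_lrc(sim$data, config = cfg)
  swapped <- sim$data
  swapped$genotype <- c(G1 = "Gb", G2 = "Ga")[swapped$genotype]
  swapped$plant <- sub("^G1", "Gb", swapped$plant)
  swapped$plant <- sub("^G2", "Ga", swapped$plant)
  f2 <- fit_lrc(swapped, config = cfg)
  # same plants in the same data order: identical chains, renamed columns
  expect_identical(unname(f1$draws[, , "mu_a_max[G1]"]),
                   unname(f2$draws[, , "mu_a_max[Gb]"]))
  expect_identical(unname(f1$draws[, , "mu_r_d[G2]"]),
                   unname(f2$draws[, , "mu_r_d[Ga]"]))
})

test_that("a single-genotype fit recovers the generating a_max", {
  # 5 plants stepped through the full chamber ladder plus a darkness point
  # (11 levels, 55 obs): darkness pins Rd and the high-light points pin the
  # plateau, so a_max is well identified
  cfg <- tiny_ladder_config(seed = 25, n_genotypes = 1, n_replicates = 5,
                            ladder = c(light_ladder_growth_chamber(), 0),
                            noise_sd = 0.5)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$data), 55)
  fit <- fit_lrc(sim$data, config = fit_config(n_chains = 2, n_adapt = 1500,
                                               n_iter = 600, thin = 3,
                                               seed = 31))
  post_mean <- mean(posterior_matrix(fit)[, "mu_a_max[G1]"])
  truth <- sim$truth$genotype_means["G1", "a_max"]
  expect_lt(abs(post_mean - truth) / truth, 0.10)
})

test_that("grid posterior normalises exactly and reduces to the prior without data", {
  pr <- prior_spec()
  empty <- data.frame(genotype = character(0), plant = character(0),
                      PARi = numeric(0), A = numeric(0))
  g <- grid_posterior_oracle(empty, pr, alpha = 0.05, theta = 0.8,
                             tau_obs = 1, n_grid = 401)
  expect_lt(abs(sum(g$posterior) - 1), 1e-9)
  # truncated-normal prior mean, computed analytically
  tn_mean <- function(m, s, lo, up) {
    a <- (lo - m) / s; b <- (up - m) / s
    m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  expect_lt(abs(g$mean[["a_max"]] -
                tn_mean(pr$mean[["a_max"]], pr$sd[["a_max"]], 0, 100)), 0.2)
  expect_lt(abs(g$mean[["r_d"]] -
                tn_mean(pr$mean[["r_d"]], pr$sd[["r_d"]], 0, 10)), 0.05)
  expect_error(grid_posterior_oracle(empty, pr, alpha = 0.05, theta = 0.8,
                                     tau_obs = 1, n_grid = 40), "coarse")
})
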