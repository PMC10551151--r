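#' Fit the hierarchical Bayesian light-response model by MCMC
#'
#' Samples the joint posterior of all plant-level curve parameters,
#' genotype-level means, genotype-level precisions and the observation
#' precision, given gas-exchange data, by adaptive Metropolis-within-Gibbs:
#' vectorised random-walk Metropolis updates for plant parameters (plants are
#' conditionally independent given their genotype) plus a joint per-plant
#' proposal along a covariance learned during burn-in (the four curve
#' parameters are strongly correlated a posteriori), random walks for the
#' genotype means, a
#' conjugate gamma Gibbs update for the observation precision, and log-scale
#' Metropolis updates for the genotype-level precisions (the truncation
#' normalisation breaks their conjugacy). Proposal scales adapt during
#' `n_adapt` burn-in iterations only, then freeze, so the retained chain is a
#' valid Markov chain. Chains use seeds derived from `config$seed` and the
#' run is deterministic given that seed.
#'
#' @param data Gas-exchange observations; see [validate_dataset()].
#' @param priors An [prior_spec()] object.
#' @param config An [fit_config()] object.
#' @return An object of class `lrc_draws`: a `chains x n_iter x parameter`
#'   array (`$draws`, dimnames carry parameter names such as `a_max[G1.P1]`,
#'   `mu_a_max[G1]`, `tau_r_d`, `tau_obs`) plus the configuration, priors,
#'   plant/genotype index and per-block acceptance rates.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_genotypes = 2, n_replicates = 2,
#'                                    seed = 7))
#' fit <- fit_lrc(sim$data,
#'                config = fit_config(n_chains = 2, n_adapt = 200,
#'                                    n_iter = 100, thin = 1, seed = 7))
#' bgr_diagnostic(fit)
fit_lrc <- function(data, priors = prior_spec(), config = fit_config()) {
  stopifnot(inherits(priors, "lrc_priors"), inherits(config, "lrc_fit_config"))
  data <- validate_dataset(data)
  if (nrow(data) == 0) stop("empty dataset: nothing to fit")
  idx <- .build_index(data)
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  chains <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    res <- .run_chain(data$PARi, data$A, idx, priors, config)
    chains[[ch]] <- res$draws
    accept[[ch]] <- res$accept
  }
  draws <- array(NA_real_,
                 dim = c(config$n_chains, config$n_iter, ncol(chains[[1]])),
                 dimnames = list(chain = NULL, iteration = NULL,
                                 parameter = colnames(chains[[1]])))
  for (ch in seq_len(config$n_chains)) draws[ch, , ] <- chains[[ch]]
  structure(list(draws = draws,
                 par_names = colnames(chains[[1]]),
                 plant_labs = idx$plant_labs,
                 geno_labs = idx$geno_labs,
                 g_of_p = idx$g_of_p,
                 config = config, priors = priors,
                 acceptance = accept),
            class = "lrc_draws")
}

# One MCMC chain. par_obs/an: observation vectors; idx: .build_index() output.
.run_chain <- function(par_obs, an, idx, priors, cfg) {
  kn <- .lrc_par_names
  P <- length(idx$plant_labs); G <- length(idx$geno_labs); N <- length(an)
  p_of_i <- idx$p_of_i; g_of_p <- idx$g_of_p
  lo <- priors$lower; up <- priors$upper
  m0 <- priors$mean; s0 <- priors$sd
  a0 <- priors$prec_shape; b0 <- priors$prec_rate
  fixed <- cfg$fixed

  # --- initial state (jittered around prior means), fixed overrides last ---
  jit <- function(v, frac = 0.05, l, u) {
    pmin(pmax(v * (1 + frac * rnorm(length(v))), l + 1e-9 * (u - l)),
         u - 1e-9 * (u - l))
  }
  theta_p <- matrix(rep(unname(m0), each = P), P, 4L,
                    dimnames = list(idx$plant_labs, kn))
  mu_g <- matrix(rep(unname(m0), each = G), G, 4L,
                 dimnames = list(idx$geno_labs, kn))
  for (k in seq_along(kn)) {
    theta_p[, k] <- jit(theta_p[, k], 0.05, lo[[k]], up[[k]])
    mu_g[, k] <- jit(mu_g[, k], 0.05, lo[[k]], up[[k]])
  }
  tau_g <- setNames(1 / (0.2 * unname(m0))^2 * exp(0.1 * rnorm(4)), kn)
  tau_o <- exp(0.1 * rnorm(1))

  upd_plant <- setNames(!(kn %in% names(fixed)), kn)
  upd_mu <- setNames(!(paste0("mu_", kn) %in% names(fixed)), kn)
  upd_taug <- setNames(!(paste0("tau_", kn) %in% names(fixed)), kn)
  upd_tauo <- !("tau_obs" %in% names(fixed))
  for (k in kn) {
    if (!upd_plant[[k]]) theta_p[, k] <- fixed[[k]]
    if (!upd_mu[[k]]) mu_g[, k] <- fixed[[paste0("mu_", k)]]
    if (!upd_taug[[k]]) tau_g[[k]] <- fixed[[paste0("tau_", k)]]
  }
  if (!upd_tauo) tau_o <- fixed$tau_obs

  # --- proposal scales (adapted during burn-in) ---
  s_plant <- setNames(c(1, 0.005, 0.3, 0.05), kn)
  s_mu <- s_plant
  s_taug <- setNames(rep(0.8, 4), kn)
  acc_cnt <- prop_cnt <- setNames(numeric(10), c(paste0("plant_", kn),
                                                 paste0("mu_", kn), "tau_g",
                                                 "plant_joint"))
  samp_acc <- samp_prop <- acc_cnt

  # Per-plant joint proposals: covariance learned from the burn-in history
  # (Haario-style adaptive Metropolis; the plant parameters are strongly
  # correlated a posteriori, so axis-aligned walks alone mix poorly).
  use_joint <- all(upd_plant)
  s_joint <- 1
  hist_n <- 0L
  hist_mean <- matrix(0, P, 4L)
  hist_m2 <- array(0, c(P, 4L, 4L))
  chol_arr <- NULL          # P x 4 x 4 upper-triangular factors
  has_chol <- rep(FALSE, P)
  build_chol <- function() {
    if (hist_n < 100L) return(NULL)
    arr <- array(0, c(P, 4L, 4L))
    okp <- rep(FALSE, P)
    for (p in seq_len(P)) {
      S <- hist_m2[p, , ] / (hist_n - 1L) * (2.38^2 / 4)
      diag(S) <- diag(S) + pmax(diag(S) * 1e-6, 1e-12)
      R <- tryCatch(chol(S), error = function(e) NULL)
      if (!is.null(R)) { arr[p, , ] <- R; okp[p] <- TRUE }
    }
    list(arr = arr, ok = okp)
  }

  mu_obs <- .nrh(theta_p[p_of_i, 1], theta_p[p_of_i, 2], theta_p[p_of_i, 3],
                 theta_p[p_of_i, 4], par_obs)

  # dense indicator matrices: group sums as BLAS products
  ind_obs <- matrix(0, N, P); ind_obs[cbind(seq_len(N), p_of_i)] <- 1
  ind_pg <- matrix(0, P, G); ind_pg[cbind(seq_len(P), g_of_p)] <- 1
  n_per_g <- colSums(ind_pg)

  n_samp <- cfg$n_iter * cfg$thin
  n_raw <- cfg$n_adapt + n_samp
  par_names <- c(
    unlist(lapply(kn, function(k) paste0(k, "[", idx$plant_labs, "]"))),
    unlist(lapply(kn, function(k) paste0("mu_", k, "[", idx$geno_labs, "]"))),
    paste0("tau_", kn), "tau_obs")
  out <- matrix(NA_real_, cfg$n_iter, length(par_names),
                dimnames = list(NULL, par_names))
  batch_i <- 0L
  nm_plant <- paste0("plant_", kn)
  nm_mu <- paste0("mu_", kn)
  # gamma log density up to its constant, with log(x) supplied by the caller
  gam_c <- a0 * log(b0) - lgamma(a0)
  ldgamma <- function(x, lx) gam_c + (a0 - 1) * lx - b0 * x
  # cached per-genotype truncation normalisers, one vector per parameter
  logz_cur <- lapply(seq_len(4L), function(k)
    .ltnz(mu_g[, k], 1 / sqrt(tau_g[[k]]), lo[[k]], up[[k]]))

  for (it in seq_len(n_raw)) {
    adapting <- it <= cfg$n_adapt
    sd_o <- 1 / sqrt(tau_o)
    ll_p <- drop(dnorm(an, mu_obs, sd_o, log = TRUE) %*% ind_obs)

    # --- plant-level parameters, one vectorised sweep per parameter ---
    # (truncation normalisers are identical for current and proposed plant
    # values, so they cancel from the Metropolis ratio)
    for (k in which(upd_plant)) {
      prop <- theta_p[, k] + s_plant[[k]] * rnorm(P)
      ok <- prop > lo[[k]] & prop < up[[k]]
      prop[!ok] <- theta_p[!ok, k]
      th2 <- theta_p; th2[, k] <- prop
      mu2 <- .nrh(th2[p_of_i, 1], th2[p_of_i, 2], th2[p_of_i, 3],
                  th2[p_of_i, 4], par_obs)
      ll2_p <- drop(dnorm(an, mu2, sd_o, log = TRUE) %*% ind_obs)
      sdk <- 1 / sqrt(tau_g[[k]])
      mug_p <- mu_g[g_of_p, k]
      logr <- (ll2_p + dnorm(prop, mug_p, sdk, log = TRUE)) -
              (ll_p + dnorm(theta_p[, k], mug_p, sdk, log = TRUE))
      logr[!ok] <- -Inf
      acc <- !is.na(logr) & log(runif(P)) < logr
      if (any(acc)) {
        theta_p[acc, k] <- prop[acc]
        ai <- acc[p_of_i]
        mu_obs[ai] <- mu2[ai]
        ll_p[acc] <- ll2_p[acc]
      }
      nm <- nm_plant[k]
      if (adapting) { acc_cnt[nm] <- acc_cnt[nm] + sum(acc); prop_cnt[nm] <- prop_cnt[nm] + P }
      else { samp_acc[nm] <- samp_acc[nm] + sum(acc); samp_prop[nm] <- samp_prop[nm] + P }
    }

    # --- joint per-plant proposal along the learned covariance ---
    if (use_joint && !is.null(chol_arr)) {
      z <- matrix(rnorm(4L * P), P, 4L)
      incr <- matrix(0, P, 4L)
      for (i in 1:4) for (j in i:4) {
        incr[, j] <- incr[, j] + z[, i] * chol_arr[, i, j]
      }
      prop <- theta_p + s_joint * incr
      prop[!has_chol, ] <- theta_p[!has_chol, ]
      ok <- rep(TRUE, P)
      for (k in seq_len(4L)) ok <- ok & prop[, k] > lo[[k]] & prop[, k] < up[[k]]
      prop[!ok, ] <- theta_p[!ok, ]
      mu2 <- .nrh(prop[p_of_i, 1], prop[p_of_i, 2], prop[p_of_i, 3],
                  prop[p_of_i, 4], par_obs)
      ll2_p <- drop(dnorm(an, mu2, sd_o, log = TRUE) %*% ind_obs)
      dpri <- numeric(P)
      for (k in seq_len(4L)) {
        sdk <- 1 / sqrt(tau_g[[k]])
        dpri <- dpri + dnorm(prop[, k], mu_g[g_of_p, k], sdk, log = TRUE) -
          dnorm(theta_p[, k], mu_g[g_of_p, k], sdk, log = TRUE)
      }
      logr <- (ll2_p - ll_p) + dpri
      logr[!ok] <- -Inf
      acc <- !is.na(logr) & log(runif(P)) < logr
      if (any(acc)) {
        theta_p[acc, ] <- prop[acc, ]
        ai <- acc[p_of_i]
        mu_obs[ai] <- mu2[ai]
        ll_p[acc] <- ll2_p[acc]
      }
      if (adapting) { acc_cnt["plant_joint"] <- acc_cnt["plant_joint"] + sum(acc); prop_cnt["plant_joint"] <- prop_cnt["plant_joint"] + P }
      else { samp_acc["plant_joint"] <- samp_acc["plant_joint"] + sum(acc); samp_prop["plant_joint"] <- samp_prop["plant_joint"] + P }
    }

    # accumulate the burn-in history feeding the joint-proposal covariance
    # (first third of burn-in is discarded as transient)
    if (use_joint && adapting && it > cfg$n_adapt %/% 3L) {
      hist_n <- hist_n + 1L
      d1 <- theta_p - hist_mean
      hist_mean <- hist_mean + d1 / hist_n
      d2 <- theta_p - hist_mean
      for (i in seq_len(4L)) for (j in seq_len(4L)) {
        hist_m2[, i, j] <- hist_m2[, i, j] + d1[, i] * d2[, j]
      }
    }

    # --- genotype means (prior-only conditional, vectorised over genotypes;
    #     plant-level truncation normalisers depend on the mean, so they are
    #     carried exactly, one per genotype). These sweeps touch no likelihood
    #     terms, so several per iteration are nearly free and help the
    #     hierarchy mix. ---
    for (sweep in 1:2) for (k in which(upd_mu)) {
      prop <- mu_g[, k] + s_mu[[k]] * rnorm(G)
      ok <- prop > lo[[k]] & prop < up[[k]]
      prop[!ok] <- mu_g[!ok, k]
      sdk <- 1 / sqrt(tau_g[[k]])
      logz_pro <- .ltnz(prop, sdk, lo[[k]], up[[k]])
      cur_g <- drop(dnorm(theta_p[, k], mu_g[g_of_p, k], sdk, log = TRUE) %*% ind_pg) -
        n_per_g * logz_cur[[k]]
      pro_g <- drop(dnorm(theta_p[, k], prop[g_of_p], sdk, log = TRUE) %*% ind_pg) -
        n_per_g * logz_pro
      # the prior's own truncation normaliser is constant and cancels
      logr <- (pro_g + dnorm(prop, m0[[k]], s0[[k]], log = TRUE)) -
              (cur_g + dnorm(mu_g[, k], m0[[k]], s0[[k]], log = TRUE))
      logr[!ok] <- -Inf
      acc <- !is.na(logr) & log(runif(G)) < logr
      mu_g[acc, k] <- prop[acc]
      logz_cur[[k]][acc] <- logz_pro[acc]
      nm <- nm_mu[k]
      if (adapting) { acc_cnt[nm] <- acc_cnt[nm] + sum(acc); prop_cnt[nm] <- prop_cnt[nm] + G }
      else { samp_acc[nm] <- samp_acc[nm] + sum(acc); samp_prop[nm] <- samp_prop[nm] + G }
    }

    # --- genotype-level precisions: log-scale Metropolis (not conjugate
    #     once the truncation normaliser is kept exact) ---
    for (sweep in 1:2) for (k in which(upd_taug)) {
      lt <- log(tau_g[[k]])
      lt2 <- lt + s_taug[[k]] * rnorm(1)
      t2 <- exp(lt2)
      sdk2 <- 1 / sqrt(t2)
      mug_p <- mu_g[g_of_p, k]
      logz_pro <- .ltnz(mu_g[, k], sdk2, lo[[k]], up[[k]])
      cur <- sum(dnorm(theta_p[, k], mug_p, 1 / sqrt(tau_g[[k]]), log = TRUE)) -
             sum(n_per_g * logz_cur[[k]]) + ldgamma(tau_g[[k]], lt) + lt
      pro <- sum(dnorm(theta_p[, k], mug_p, sdk2, log = TRUE)) -
             sum(n_per_g * logz_pro) + ldgamma(t2, lt2) + lt2
      acc <- is.finite(pro) && is.finite(cur) && log(runif(1)) < pro - cur
      if (acc) { tau_g[[k]] <- t2; logz_cur[[k]] <- logz_pro }
      if (adapting) { acc_cnt["tau_g"] <- acc_cnt["tau_g"] + acc; prop_cnt["tau_g"] <- prop_cnt["tau_g"] + 1 }
      else { samp_acc["tau_g"] <- samp_acc["tau_g"] + acc; samp_prop["tau_g"] <- samp_prop["tau_g"] + 1 }
    }

    # --- observation precision: conjugate gamma Gibbs ---
    if (upd_tauo) {
      tau_o <- rgamma(1, a0 + N / 2, b0 + 0.5 * sum((an - mu_obs)^2))
    }

    # --- scale adaptation (burn-in only, in batches) ---
    if (adapting && it %% cfg$adapt_batch == 0L) {
      batch_i <- batch_i + 1L
      delta <- min(0.25, 1 / sqrt(batch_i))
      rate <- ifelse(prop_cnt > 0, acc_cnt / pmax(prop_cnt, 1), cfg$target_accept)
      for (k in which(upd_plant)) {
        nm <- nm_plant[k]
        s_plant[[k]] <- s_plant[[k]] * exp(delta * sign(rate[nm] - cfg$target_accept))
      }
      for (k in which(upd_mu)) {
        nm <- nm_mu[k]
        s_mu[[k]] <- s_mu[[k]] * exp(delta * sign(rate[nm] - cfg$target_accept))
      }
      if (any(upd_taug)) {
        s_taug[] <- s_taug * exp(delta * sign(rate["tau_g"] - cfg$target_accept))
      }
      if (use_joint) {
        if (prop_cnt["plant_joint"] > 0) {
          s_joint <- s_joint * exp(delta * sign(rate["plant_joint"] - 0.25))
        }
        bc <- build_chol()
        if (!is.null(bc)) { chol_arr <- bc$arr; has_chol <- bc$ok }
      }
      acc_cnt[] <- 0; prop_cnt[] <- 0
    }
    # freeze the joint-proposal covariance for the sampling phase
    if (use_joint && it == cfg$n_adapt) {
      bc <- build_chol()
      if (!is.null(bc)) { chol_arr <- bc$arr; has_chol <- bc$ok }
    }

    j <- it - cfg$n_adapt
    if (j > 0L && j %% cfg$thin == 0L) {
      out[j %/% cfg$thin, ] <- c(theta_p, mu_g, tau_g, tau_o)
    }
  }

  rates <- ifelse(samp_prop > 0, samp_acc / pmax(samp_prop, 1), NA_real_)
  active <- samp_prop > 0
  if (any(active) && any(rates[active] <= 0.05 | rates[active] >= 0.95)) {
    bad <- names(rates)[active & (rates <= 0.05 | rates >= 0.95)]
    stop("sampler acceptance rate outside (0.05, 0.95) after adaptation for ",
         "block(s): ", paste(bad, collapse = ", "),
         " - proposal tuning failed; increase n_adapt")
  }
  list(draws = out, accept = rates)
}

#' @export
print.lrc_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior draws: %d chains x %d retained iterations x %d parameters\n",
              d[1], d[2], d[3]))
  cat(sprintf("  plants: %d, genotypes: %d, thin: %d, seed: %d\n",
              length(x$plant_labs), length(x$geno_labs),
              x$config$thin, x$config$seed))
  invisible(x)
}

#' Pooled draw matrix from an `lrc_draws` object
#'
#' @param draws An `lrc_draws` object.
#' @return Matrix (chains x iterations) rows by parameter columns, chains
#'   stacked in order.
#' @export
posterior_matrix <- function(draws) {
  stopifnot(inherits(draws, "lrc_draws"))
  d <- dim(draws$draws)
  out <- matrix(aperm(draws$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(out) <- draws$par_names
  out
}

#' Brute-force grid posterior for a reduced two-parameter model
#'
#' Independent validation oracle for the MCMC sampler: for a single plant's
#' data with `alpha`, `theta` and the observation precision held fixed, the
#' posterior over (`a_max`, `r_d`) under the truncated-normal priors is
#' evaluated by exhaustive summation on a rectangular grid and normalised to
#' total mass 1. Marginal means and sds are returned for comparison with
#' MCMC output from the same reduced model (via `fit_config(fixed = ...)`).
#'
#' @param data Observations for exactly one plant; at most 30 rows.
#' @param priors An [prior_spec()]; its `a_max` and `r_d` entries define the
#'   priors on the two free parameters.
#' @param alpha,theta Fixed values of the other two curve parameters.
#' @param tau_obs Fixed observation precision.
#' @param a_max_grid,r_d_grid Grid points; default `n_grid` equally spaced
#'   points across the truncation bounds. Fewer than 50 points per axis is
#'   rejected as too coarse.
#' @param n_grid Default grid resolution per axis.
#' @return Object of class `lrc_grid`: grids, normalised posterior matrix
#'   (`a_max` by rows), and marginal `mean`/`sd` for both parameters.
#' @export
grid_posterior_oracle <- function(data, priors = prior_spec(), alpha, theta,
                                  tau_obs, a_max_grid = NULL, r_d_grid = NULL,
                                  n_grid = 101) {
  data <- validate_dataset(data)
  if (nrow(data) > 0 && length(unique(data$plant)) != 1L) {
    stop("grid oracle requires exactly one plant")
  }
  if (nrow(data) > 30) stop("grid oracle restricted to small datasets (<= 30 obs)")
  if (is.null(a_max_grid)) {
    a_max_grid <- seq(priors$lower[["a_max"]] + 1e-6, priors$upper[["a_max"]],
                      length.out = n_grid)
  }
  if (is.null(r_d_grid)) {
    r_d_grid <- seq(priors$lower[["r_d"]], priors$upper[["r_d"]],
                    length.out = n_grid)
  }
  if (length(a_max_grid) < 50 || length(r_d_grid) < 50) {
    stop("grid too coarse: need at least 50 points per axis")
  }
  sd_o <- 1 / sqrt(tau_obs)
  la <- .dtnorm_log(a_max_grid, priors$mean[["a_max"]], priors$sd[["a_max"]],
                    priors$lower[["a_max"]], priors$upper[["a_max"]])
  lr <- .dtnorm_log(r_d_grid, priors$mean[["r_d"]], priors$sd[["r_d"]],
                    priors$lower[["r_d"]], priors$upper[["r_d"]])
  # mu depends on r_d only through a constant shift: evaluate per a_max once
  gross <- vapply(a_max_grid, function(a) {
    .nrh(a, alpha, 0, theta, data$PARi)
  }, numeric(nrow(data)))  # n_obs x n_a
  gross <- matrix(gross, nrow = nrow(data))
  logpost <- matrix(NA_real_, length(a_max_grid), length(r_d_grid))
  for (j in seq_along(r_d_grid)) {
    resid_ll <- if (nrow(data) == 0) 0 else
      colSums(dnorm(data$A, gross - r_d_grid[j], sd_o, log = TRUE))
    logpost[, j] <- la + lr[j] + resid_ll
  }
  m <- max(logpost)
  post <- exp(logpost - m)
  post <- post / sum(post)
  pa <- rowSums(post); pr <- colSums(post)
  mean_a <- sum(pa * a_max_grid); mean_r <- sum(pr * r_d_grid)
  structure(list(
    a_max = a_max_grid, r_d = r_d_grid, posterior = post,
    mean = c(a_max = mean_a, r_d = mean_r),
    sd = c(a_max = sqrt(sum(pa * (a_max_grid - mean_a)^2)),
           r_d = sqrt(sum(pr * (r_d_grid - mean_r)^2)))),
    class = "lrc_grid")
}
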