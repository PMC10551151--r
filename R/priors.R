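#' Default support bounds for the light-response parameters
#'
#' Truncation bounds used by the priors and the synthetic-data generator:
#' a_max in (0, 100], alpha in (0, 0.125] (the theoretical quantum-yield
#' ceiling), r_d in [0, 10], theta in (0, 1).
#'
#' @return List with numeric vectors `lower` and `upper`, named by parameter.
#' @export
param_bounds <- function() {
  list(lower = c(a_max = 0, alpha = 0, r_d = 0, theta = 0),
       upper = c(a_max = 100, alpha = 0.125, r_d = 10, theta = 1))
}

#' Prior specification for the hierarchical light-response model
#'
#' Genotype-level means get truncated-normal priors centred on values typical
#' for rice with deliberately wide spread (by default sd = 2 x mean, i.e.
#' +/-200% of the mean); all precision terms get a common vague gamma prior.
#'
#' @param mean Named prior means for `a_max`, `alpha`, `r_d`, `theta`.
#' @param sd Named prior standard deviations; default `2 * mean` (for
#'   `r_d = 1.5` that is sd 3, and so on).
#' @param lower,upper Truncation bounds; default [param_bounds()].
#' @param prec_shape,prec_rate Shape and rate of the gamma prior shared by the
#'   observation precision and the four genotype-level precisions.
#'
#' @return Object of class `lrc_priors`.
#' @export
prior_spec <- function(mean = c(a_max = 25, alpha = 0.05, r_d = 1.5, theta = 0.8),
                       sd = 2 * mean,
                       lower = param_bounds()$lower,
                       upper = param_bounds()$upper,
                       prec_shape = 0.01, prec_rate = 0.01) {
  mean <- mean[.lrc_par_names]; sd <- sd[.lrc_par_names]
  lower <- lower[.lrc_par_names]; upper <- upper[.lrc_par_names]
  if (any(is.na(mean)) || any(is.na(sd))) {
    stop("prior mean and sd must be named for all of: ",
         paste(.lrc_par_names, collapse = ", "))
  }
  if (any(sd <= 0)) stop("prior sd must be > 0")
  if (any(lower >= upper)) stop("lower bound must be below upper bound")
  if (any(mean < lower | mean > upper)) {
    stop("prior means must lie inside the truncation bounds")
  }
  if (prec_shape <= 0 || prec_rate <= 0) stop("precision prior shape/rate must be > 0")
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper,
                 prec_shape = prec_shape, prec_rate = prec_rate),
            class = "lrc_priors")
}

#' MCMC sampler configuration
#'
#' @param n_chains Number of independent chains; >= 2 (the BGR diagnostic
#'   needs several).
#' @param n_adapt Adaptation/burn-in iterations per chain (proposal scales are
#'   tuned here, then frozen; these draws are discarded).
#' @param n_iter Retained draws per chain *after* thinning, the way chain
#'   length is usually quoted (e.g. 10,000 retained x 3 chains = 30,000
#'   pooled).
#' @param thin Keep every `thin`-th post-adaptation iteration; >= 1. The chain
#'   runs `n_iter * thin` sampling iterations.
#' @param seed Integer seed; per-chain streams are derived from it.
#' @param fixed Named list of parameters to hold fixed (their updates are
#'   skipped). Recognised names: `tau_obs`; `tau_<p>`, `mu_<p>` (scalar applied
#'   to every genotype) and `<p>` (scalar applied to every plant) for each
#'   parameter `<p>` in `a_max`, `alpha`, `r_d`, `theta`. Used for reduced
#'   models, e.g. validating the sampler against a grid posterior.
#' @param target_accept Target Metropolis acceptance rate during adaptation.
#' @param adapt_batch Iterations per adaptation batch.
#'
#' @return Object of class `lrc_fit_config`.
#' @export
fit_config <- function(n_chains = 3, n_adapt = 2000, n_iter = 10000, thin = 10,
                       seed = 1L, fixed = list(), target_accept = 0.35,
                       adapt_batch = 50L) {
  if (n_chains < 2) stop("n_chains must be >= 2 (multi-chain diagnostics)")
  if (n_iter < 1) stop("n_iter must be >= 1: nothing to retain")
  if (thin < 1) stop("thin must be >= 1")
  if (n_adapt < 0) stop("n_adapt must be >= 0")
  if (target_accept <= 0 || target_accept >= 1) stop("target_accept in (0,1)")
  allowed <- c("tau_obs",
               paste0("tau_", .lrc_par_names),
               paste0("mu_", .lrc_par_names),
               .lrc_par_names)
  bad <- setdiff(names(fixed), allowed)
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  structure(list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seed = as.integer(seed), fixed = fixed,
                 target_accept = target_accept,
                 adapt_batch = as.integer(adapt_batch)),
            class = "lrc_fit_config")
}
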