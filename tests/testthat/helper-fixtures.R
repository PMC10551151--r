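# Shared fixtures: all synthetic, built in code at test time.

# Small canned simulation configs
tiny_field_config <- function(seed = 42, n_genotypes = 2, n_replicates = 2) {
  sim_config(n_genotypes = n_genotypes, n_replicates = n_replicates,
             design = design_nonsequential(), seed = seed)
}

tiny_ladder_config <- function(seed = 42, n_genotypes = 1, n_replicates = 2,
                               ladder = light_ladder_greenhouse(), ...) {
  sim_config(n_genotypes = n_genotypes, n_replicates = n_replicates,
             design = design_sequential(ladder), seed = seed, ...)
}

# Random valid curve parameters for property tests
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lrc_params(a_max = runif(1, 5, 60), alpha = runif(1, 0.01, 0.12),
               r_d = runif(1, 0, 5), theta = runif(1, 0.05, 1))
  })
}

# Wrap one latent state (or a plain series) into the posterior-draws container,
# repeating it across chains/iterations; used to test downstream stages with
# exactly known "posteriors".
draws_from_state <- function(state, n_chains = 2, n_iter = 2) {
  kn <- c("a_max", "alpha", "r_d", "theta")
  pl <- rownames(state$plant_params)
  gl <- rownames(state$genotype_means)
  v <- c(as.vector(state$plant_params), as.vector(state$genotype_means),
         state$genotype_precisions, state$obs_precision)
  nms <- c(unlist(lapply(kn, function(k) paste0(k, "[", pl, "]"))),
           unlist(lapply(kn, function(k) paste0("mu_", k, "[", gl, "]"))),
           paste0("tau_", kn), "tau_obs")
  arr <- array(rep(v, each = n_chains * n_iter),
               dim = c(n_chains, n_iter, length(v)),
               dimnames = list(NULL, NULL, nms))
  structure(list(draws = arr, par_names = nms, plant_labs = pl,
                 geno_labs = gl,
                 config = fit_config(n_chains = n_chains, n_iter = n_iter,
                                     thin = 1),
                 priors = prior_spec(), acceptance = NULL),
            class = "lrc_draws")
}

draws_from_series <- function(x, n_chains = 2) {
  arr <- array(rep(x, each = n_chains), dim = c(n_chains, length(x), 1),
               dimnames = list(NULL, NULL, "x"))
  structure(list(draws = arr, par_names = "x", plant_labs = character(0),
                 geno_labs = character(0),
                 config = fit_config(n_chains = n_chains, n_iter = length(x),
                                     thin = 1),
                 priors = prior_spec(), acceptance = NULL),
            class = "lrc_draws")
}

# Row-wise curve evaluation for a matrix of per-observation parameters
nrh_mean_vecparams <- function(pp, par) {
  lrcbayes:::.nrh(pp[, "a_max"], pp[, "alpha"], pp[, "r_d"], pp[, "theta"], par)
}
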