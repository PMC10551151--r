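#' Measurement-design descriptions for the synthetic generator
#'
#' `design_nonsequential()` is the field survey design: each plant is measured
#' a few times at its ambient light while the diurnal cycle sweeps irradiance
#' across the stated range. `design_sequential()` steps one leaf through a
#' fixed ladder of chamber light levels.
#'
#' @param n_measurements Measurements per plant (non-sequential).
#' @param par_min,par_max Ambient PAR range, umol photon m^-2 s^-1.
#' @param light_levels Ordered chamber light ladder (sequential).
#' @return A design description list.
#' @export
design_nonsequential <- function(n_measurements = 3, par_min = 1, par_max = 2400) {
  if (n_measurements < 1) stop("n_measurements must be >= 1")
  if (par_min >= par_max) stop("par_min must be < par_max")
  if (par_min < 0) stop("PAR must be >= 0")
  list(type = "nonsequential", n_measurements = as.integer(n_measurements),
       par_min = par_min, par_max = par_max)
}

#' @rdname design_nonsequential
#' @export
design_sequential <- function(light_levels) {
  if (length(light_levels) < 1 || any(light_levels < 0)) {
    stop("light_levels must be a non-empty vector of PAR values >= 0")
  }
  list(type = "sequential", light_levels = as.numeric(light_levels))
}

#' Standard chamber light ladders
#'
#' The auto-program ladders used for sequential curves: the growth-chamber
#' ladder (2000 down to 50 umol m^-2 s^-1) and the greenhouse rapid ladder
#' (1400 down to full darkness).
#'
#' @return Numeric vector of PAR levels in measurement order.
#' @export
light_ladder_growth_chamber <- function() {
  c(2000, 1600, 1400, 1200, 1000, 800, 600, 400, 200, 50)
}

#' @rdname light_ladder_growth_chamber
#' @export
light_ladder_greenhouse <- function() {
  c(1400, 1200, 1000, 800, 600, 400, 200, 100, 50, 0)
}

#' Configuration for the synthetic gas-exchange generator
#'
#' Defaults emulate the field survey study design: 7 rice genotypes x 5
#' replicate plants, 3 measurements per plant at ambient PAR spanning
#' 1-2400 umol m^-2 s^-1, so each genotype contributes a 15-point curve.
#' Plant-level parameters vary around genotype-level means, which vary around
#' the stated hyper-means; all draws are truncated to the parameter support.
#'
#' @param n_genotypes,n_replicates Counts; >= 1.
#' @param design A [design_nonsequential()] or [design_sequential()] list.
#' @param noise_sd Observation noise sd (1/sqrt(tau)), umol CO2 m^-2 s^-1.
#' @param hyper_mean,hyper_sd Named genotype-level means and sds for
#'   `a_max`, `alpha`, `r_d`, `theta` (the recovery-test ground truth).
#' @param plant_sd Within-genotype (plant-level) sds; default half the
#'   genotype-level sds.
#' @param environment Environment label attached to every observation.
#' @param temp_range,vpd_range Ranges for the optional air-temperature and
#'   VPD covariates (uniform draws; not used by the model).
#' @param seed Integer RNG seed used by [simulate_dataset()].
#'
#' @return Object of class `lrc_sim_config`.
#' @export
sim_config <- function(n_genotypes = 7, n_replicates = 5,
                       design = design_nonsequential(),
                       noise_sd = 1.0,
                       hyper_mean = c(a_max = 25, alpha = 0.05, r_d = 1.5, theta = 0.8),
                       hyper_sd = c(a_max = 3, alpha = 0.005, r_d = 0.3, theta = 0.05),
                       plant_sd = hyper_sd / 2,
                       environment = "field",
                       temp_range = c(24, 36), vpd_range = c(0.79, 3.5),
                       seed = 1L) {
  if (n_genotypes < 1 || n_replicates < 1) stop("counts must be >= 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  hyper_mean <- hyper_mean[.lrc_par_names]
  hyper_sd <- hyper_sd[.lrc_par_names]
  plant_sd <- plant_sd[.lrc_par_names]
  if (any(is.na(hyper_mean)) || any(is.na(hyper_sd)) || any(is.na(plant_sd))) {
    stop("hyper_mean, hyper_sd and plant_sd must be named for all parameters")
  }
  if (any(hyper_sd < 0) || any(plant_sd < 0)) stop("sds must be >= 0")
  vp <- validate_params(as.list(hyper_mean))
  if (length(vp)) stop("hyper_mean invalid: ", paste(vp, collapse = "; "))
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_replicates = as.integer(n_replicates),
                 design = design, noise_sd = noise_sd,
                 hyper_mean = hyper_mean, hyper_sd = hyper_sd,
                 plant_sd = plant_sd, environment = environment,
                 temp_range = temp_range, vpd_range = vpd_range,
                 seed = as.integer(seed)),
            class = "lrc_sim_config")
}

#' Draw genotype-level parameter means
#'
#' One mean parameter set per genotype, each parameter drawn from a normal
#' around the hyper-mean and truncated to the parameter support by rejection.
#' Uses the current RNG state; seed externally (or via [simulate_dataset()])
#' for reproducibility.
#'
#' @param config An [sim_config()] object.
#' @return Matrix `n_genotypes` x 4 with rownames `G1..Gn` and columns
#'   `a_max`, `alpha`, `r_d`, `theta`.
#' @export
draw_genotype_params <- function(config) {
  b <- param_bounds()
  G <- config$n_genotypes
  out <- matrix(NA_real_, G, 4L,
                dimnames = list(paste0("G", seq_len(G)), .lrc_par_names))
  for (k in .lrc_par_names) {
    out[, k] <- .rtnorm(G, config$hyper_mean[[k]], config$hyper_sd[[k]],
                        b$lower[[k]], b$upper[[k]])
  }
  out
}

#' Draw plant-level parameters around genotype means
#'
#' Each replicate plant's parameters are normal around its genotype mean with
#' sd `config$plant_sd`, truncated to the parameter support. Plant labels are
#' globally unique (`G1.P1`, ...).
#'
#' @param genotype_means Matrix from [draw_genotype_params()].
#' @param config An [sim_config()] object.
#' @return Matrix (`n_genotypes * n_replicates`) x 4, rownames `G<g>.P<r>`.
#' @export
draw_plant_params <- function(genotype_means, config) {
  b <- param_bounds()
  G <- nrow(genotype_means); R <- config$n_replicates
  g_of_p <- rep(seq_len(G), each = R)
  labs <- paste0(rownames(genotype_means)[g_of_p], ".P",
                 rep(seq_len(R), times = G))
  out <- matrix(NA_real_, G * R, 4L, dimnames = list(labs, .lrc_par_names))
  for (k in .lrc_par_names) {
    out[, k] <- .rtnorm(G * R, genotype_means[g_of_p, k], config$plant_sd[[k]],
                        b$lower[[k]], b$upper[[k]])
  }
  out
}

#' Diurnal ambient-PAR sampler
#'
#' Proxy for the light a survey measurement encounters across a day:
#' `par_min + (par_max - par_min) * sin(pi * u) * (1 + j)` with
#' `u ~ Uniform(0,1)` a time-of-day proxy and jitter `j ~ Uniform(-0.1, 0.1)`,
#' clipped to `[par_min, par_max]`. Morning/evening measurements land near
#' `par_min`, midday near `par_max`.
#'
#' @param n Number of values; >= 1.
#' @param par_min,par_max PAR range.
#' @return Numeric vector of PAR values in `[par_min, par_max]`.
#' @export
diurnal_par_sampler <- function(n, par_min = 1, par_max = 2400) {
  if (n < 1) stop("n must be >= 1")
  if (par_min >= par_max) stop("par_min must be < par_max")
  u <- runif(n)
  j <- runif(n, -0.1, 0.1)
  p <- par_min + (par_max - par_min) * sin(pi * u) * (1 + j)
  pmin(pmax(p, par_min), par_max)
}

#' Simulate a gas-exchange dataset with known ground truth
#'
#' Seeds the RNG from `config$seed`, draws the genotype and plant parameter
#' hierarchy, assigns PAR values per the design (diurnal samples for the
#' non-sequential survey; the full ladder per plant for sequential curves),
#' and adds Gaussian observation noise to the model mean.
#'
#' @param config An [sim_config()] object.
#' @return List with `data` (a data.frame with columns `obs_id`, `genotype`,
#'   `plant`, `environment`, `PARi`, `A`, `Tair`, `VPD`) and `truth` (an
#'   `lrc_state`: the plant/genotype parameters and precisions that generated
#'   the data).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_genotypes = 2, n_replicates = 2))
#' head(sim$data)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "lrc_sim_config"))
  set.seed(config$seed)
  geno <- draw_genotype_params(config)
  plants <- draw_plant_params(geno, config)
  P <- nrow(plants)
  des <- config$design
  if (des$type == "nonsequential") {
    m <- des$n_measurements
    par_vals <- diurnal_par_sampler(P * m, des$par_min, des$par_max)
  } else {
    m <- length(des$light_levels)
    par_vals <- rep(des$light_levels, times = P)
  }
  p_of_i <- rep(seq_len(P), each = m)
  mu <- .nrh(plants[p_of_i, "a_max"], plants[p_of_i, "alpha"],
             plants[p_of_i, "r_d"], plants[p_of_i, "theta"], par_vals)
  a_n <- mu + rnorm(length(mu), 0, config$noise_sd)
  g_of_p <- match(sub("\\.P[0-9]+$", "", rownames(plants)), rownames(geno))
  data <- data.frame(
    obs_id = seq_along(a_n),
    genotype = rownames(geno)[g_of_p][p_of_i],
    plant = rownames(plants)[p_of_i],
    environment = config$environment,
    PARi = par_vals,
    A = a_n,
    Tair = runif(length(a_n), config$temp_range[1], config$temp_range[2]),
    VPD = runif(length(a_n), config$vpd_range[1], config$vpd_range[2]),
    stringsAsFactors = FALSE
  )
  truth <- lrc_state(
    plant_params = plants,
    genotype_means = geno,
    genotype_precisions = ifelse(config$plant_sd > 0, 1 / config$plant_sd^2, Inf),
    obs_precision = 1 / config$noise_sd^2
  )
  list(data = data, truth = truth)
}
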