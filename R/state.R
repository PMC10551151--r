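#' Full latent state of the hierarchical light-response model
#'
#' @param plant_params Numeric matrix, one row per plant (rownames are the
#'   plant labels used in the data), columns `a_max`, `alpha`, `r_d`, `theta`.
#' @param genotype_means Numeric matrix, one row per genotype (rownames are
#'   genotype labels), same columns.
#' @param genotype_precisions Named numeric vector: precision (1/variance) of
#'   the plant-level distribution for each parameter; > 0.
#' @param obs_precision Observation precision tau of the likelihood; > 0.
#' @return Object of class `lrc_state`.
#' @export
lrc_state <- function(plant_params, genotype_means, genotype_precisions,
                      obs_precision) {
  s <- structure(list(plant_params = plant_params,
                      genotype_means = genotype_means,
                      genotype_precisions = genotype_precisions[.lrc_par_names],
                      obs_precision = obs_precision),
                 class = "lrc_state")
  viol <- validate_state(s)
  if (length(viol)) stop("invalid state: ", paste(viol, collapse = "; "))
  s
}

#' @rdname lrc_state
#' @param state An `lrc_state` (or compatible list).
#' @return `validate_state()`: character vector of violations, empty iff valid.
#' @export
validate_state <- function(state) {
  viol <- character(0)
  for (m in c("plant_params", "genotype_means")) {
    x <- state[[m]]
    if (!is.matrix(x) || !identical(colnames(x), .lrc_par_names) ||
        is.null(rownames(x))) {
      return(paste0(m, " must be a matrix with rownames and columns ",
                    paste(.lrc_par_names, collapse = ", ")))
    }
  }
  pp <- state$plant_params
  if (any(pp[, "a_max"] <= 0)) viol <- c(viol, "a_max must be > 0")
  if (any(pp[, "alpha"] <= 0)) viol <- c(viol, "alpha must be > 0")
  if (any(pp[, "r_d"] < 0)) viol <- c(viol, "r_d must be >= 0")
  if (any(pp[, "theta"] <= 0 | pp[, "theta"] > 1)) {
    viol <- c(viol, "theta must be in (0, 1]")
  }
  if (any(state$genotype_precisions <= 0) || state$obs_precision <= 0) {
    viol <- c(viol, "all precisions must be > 0")
  }
  viol
}

#' Validate a gas-exchange dataset
#'
#' Checks the tabular contract used throughout the package: columns
#' `genotype`, `plant`, `PARi`, `A` (plus optional `obs_id`, `environment`,
#' `Tair`, `VPD`); PAR >= 0 and finite A; non-empty labels; no duplicate
#' `obs_id`; every plant label belonging to exactly one genotype.
#'
#' @param data A data.frame of observations.
#' @return The data (with `obs_id` and `environment` filled in if absent),
#'   invisibly classed; raises on violations.
#' @export
validate_dataset <- function(data) {
  if (!is.data.frame(data)) stop("data must be a data.frame")
  need <- c("genotype", "plant", "PARi", "A")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0) return(data)
  if (is.null(data$obs_id)) data$obs_id <- seq_len(nrow(data))
  if (anyDuplicated(data$obs_id)) stop("duplicate obs_id values")
  if (is.null(data$environment)) data$environment <- "unknown"
  if (any(!is.finite(data$PARi)) || any(data$PARi < 0)) {
    stop("PARi must be finite and >= 0")
  }
  if (any(!is.finite(data$A))) stop("A must be finite")
  if (any(!nzchar(data$genotype)) || any(!nzchar(data$plant))) {
    stop("genotype and plant labels must be non-empty")
  }
  tab <- unique(data[, c("genotype", "plant")])
  if (anyDuplicated(tab$plant)) {
    stop("plant label(s) mapped to more than one genotype: ",
         paste(unique(tab$plant[duplicated(tab$plant)]), collapse = ", "))
  }
  data
}

# Index plants and genotypes in order of first appearance (keeps the sampler's
# RNG stream independent of label spelling, so relabelling permutes posteriors).
.build_index <- function(data) {
  plant_labs <- unique(data$plant)
  p_of_i <- match(data$plant, plant_labs)
  geno_of_plant_lab <- data$genotype[match(plant_labs, data$plant)]
  geno_labs <- unique(geno_of_plant_lab)
  g_of_p <- match(geno_of_plant_lab, geno_labs)
  list(plant_labs = plant_labs, geno_labs = geno_labs,
       p_of_i = p_of_i, g_of_p = g_of_p)
}


#' Log likelihood of a dataset given a latent state
#'
#' Sum over observations of the Gaussian log density of the measured net
#' photosynthesis around the non-rectangular hyperbola mean of that
#' observation's plant, with shared precision `obs_precision`.
#'
#' @param state An [lrc_state()] whose `plant_params` rownames cover every
#'   plant label in `data`.
#' @param data A dataset accepted by [validate_dataset()].
#' @return Scalar log density (finite for valid inputs).
#' @export
log_likelihood <- function(state, data) {
  data <- validate_dataset(data)
  idx <- match(data$plant, rownames(state$plant_params))
  if (any(is.na(idx))) {
    stop("plant(s) in data without parameters in state: ",
         paste(unique(data$plant[is.na(idx)]), collapse = ", "))
  }
  pp <- state$plant_params
  mu <- .nrh(pp[idx, "a_max"], pp[idx, "alpha"], pp[idx, "r_d"],
             pp[idx, "theta"], data$PARi)
  sum(dnorm(data$A, mu, 1 / sqrt(state$obs_precision), log = TRUE))
}

#' Log prior density of a latent state
#'
#' Sum of (a) truncated-normal log densities of each plant parameter around
#' its genotype mean with the parameter's genotype-level precision, (b)
#' truncated-normal log densities of the genotype means under the prior, and
#' (c) gamma log densities of the five precision terms. Truncation
#' normalising constants are included exactly. States violating any
#' truncation bound score `-Inf`.
#'
#' @param state An [lrc_state()]; plant rownames must identify their genotype
#'   as `<genotype>.<plant>` or via the `genotype_of_plant` attribute set by
#'   the fitting machinery. The simplest contract: `genotype_means` rownames
#'   must be prefixes (`G1.P2` belongs to `G1`).
#' @param priors An [prior_spec()] object.
#' @param genotype_of_plant Optional character vector mapping each plant row
#'   to its genotype label; inferred from rowname prefixes when omitted.
#' @return Scalar log density, `-Inf` on truncation violations.
#' @export
log_prior <- function(state, priors, genotype_of_plant = NULL) {
  stopifnot(inherits(priors, "lrc_priors"))
  pp <- state$plant_params
  gm <- state$genotype_means
  if (is.null(genotype_of_plant)) {
    genotype_of_plant <- sub("\\.[^.]+$", "", rownames(pp))
  }
  g_idx <- match(genotype_of_plant, rownames(gm))
  if (any(is.na(g_idx))) stop("could not map every plant to a genotype")
  lp <- 0
  for (k in .lrc_par_names) {
    sdk <- 1 / sqrt(state$genotype_precisions[[k]])
    lp <- lp + sum(.dtnorm_log(pp[, k], gm[g_idx, k], sdk,
                               priors$lower[[k]], priors$upper[[k]]))
    lp <- lp + sum(.dtnorm_log(gm[, k], priors$mean[[k]], priors$sd[[k]],
                               priors$lower[[k]], priors$upper[[k]]))
    lp <- lp + dgamma(state$genotype_precisions[[k]], priors$prec_shape,
                      priors$prec_rate, log = TRUE)
  }
  lp + dgamma(state$obs_precision, priors$prec_shape, priors$prec_rate,
              log = TRUE)
}
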