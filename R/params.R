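#' Light-response curve parameters for one plant
#'
#' Bundles the four parameters of the non-rectangular hyperbola light
#' response model.
#'
#' @param a_max Maximum gross assimilation rate, umol CO2 m^-2 s^-1; > 0.
#' @param alpha Apparent quantum yield (initial slope), umol CO2 umol
#'   photon^-1; > 0.
#' @param r_d Mitochondrial (dark) respiration, umol CO2 m^-2 s^-1; >= 0.
#' @param theta Curvature shape parameter, unitless; 0 < theta <= 1.
#'   theta = 0 is the rectangular hyperbola limit, theta = 1 the Blackman
#'   (two-line) response.
#'
#' @return An object of class `lrc_params`.
#' @seealso [nrh_mean()], [validate_params()]
#' @export
#' @examples
#' p <- lrc_params(a_max = 25, alpha = 0.05, r_d = 1.5, theta = 0.8)
#' nrh_mean(p, par = c(0, 500, 2000))
lrc_params <- function(a_max, alpha, r_d, theta) {
  p <- structure(list(a_max = a_max, alpha = alpha, r_d = r_d, theta = theta),
                 class = "lrc_params")
  viol <- validate_params(p)
  if (length(viol)) {
    stop("invalid light-response parameters: ", paste(viol, collapse = "; "))
  }
  p
}

#' @export
print.lrc_params <- function(x, ...) {
  cat(sprintf(
    "Light-response parameters: Amax = %g, alpha = %g, Rd = %g, theta = %g\n",
    x$a_max, x$alpha, x$r_d, x$theta))
  invisible(x)
}

#' Check light-response parameter constraints
#'
#' Total function: returns every violated constraint rather than raising.
#' Accepts an [lrc_params()] object or any list with fields `a_max`,
#' `alpha`, `r_d`, `theta`.
#'
#' @param params Parameter set to check.
#' @return Character vector of violations; `character(0)` iff valid.
#' @export
#' @examples
#' validate_params(list(a_max = 20, alpha = 0.05, r_d = 1.5, theta = 1.5))
validate_params <- function(params) {
  viol <- character(0)
  need <- .lrc_par_names
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    return(paste0("missing field: ", miss))
  }
  num_ok <- vapply(params[need],
                   function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                   logical(1))
  if (any(!num_ok)) {
    return(paste0("non-finite or non-scalar field: ", need[!num_ok]))
  }
  if (params$a_max <= 0) viol <- c(viol, "a_max must be > 0")
  if (params$alpha <= 0) viol <- c(viol, "alpha must be > 0")
  if (params$r_d < 0) viol <- c(viol, "r_d must be >= 0")
  if (params$theta <= 0) viol <- c(viol, "theta must be > 0")
  if (params$theta > 1) viol <- c(viol, "theta must be <= 1")
  viol
}

# Vectorised non-rectangular hyperbola. All arguments recycle; no validation
# (hot path inside the sampler). Smaller root of
#   theta z^2 - (alpha I + Amax) z + alpha I Amax = 0, minus Rd.
# For theta below eps_theta the rectangular-hyperbola limit is used (the
# quadratic formula degenerates to 0/0 there).
.nrh <- function(a_max, alpha, r_d, theta, par, eps_theta = 1e-6) {
  q <- alpha * par + a_max
  disc <- q * q - 4 * theta * alpha * par * a_max
  if (any(neg <- disc < 0)) {
    if (any(disc < -1e-10)) {
      stop("negative discriminant in non-rectangular hyperbola (invalid parameters)")
    }
    disc[neg] <- 0
  }
  if (any(small <- theta < eps_theta)) {
    mu <- (q - sqrt(disc)) / (2 * pmax(theta, eps_theta)) - r_d
    mu0 <- rep_len(alpha * par * a_max / q - r_d, length(mu))
    sm <- rep_len(small, length(mu))
    mu[sm] <- mu0[sm]
    return(mu)
  }
  (q - sqrt(disc)) / (2 * theta) - r_d
}

#' Mean net assimilation under the non-rectangular hyperbola
#'
#' The deterministic process model: net photosynthesis as a function of
#' irradiance,
#' \deqn{\mu(I) = \frac{\alpha I + A_{max} -
#'   \sqrt{(\alpha I + A_{max})^2 - 4\theta\alpha I A_{max}}}{2\theta} - R_d,}
#' the smaller root of the quadratic \eqn{\theta z^2 - (\alpha I + A_{max}) z
#' + \alpha I A_{max} = 0} (the larger root is non-physical, exceeding
#' \eqn{A_{max}}). For `theta` below `1e-6` the rectangular-hyperbola limit
#' [nrh_mean_theta_zero()] is returned to avoid 0/0. A discriminant more
#' negative than `-1e-10` raises; slight negatives from round-off are clamped
#' to zero.
#'
#' @param params An [lrc_params()] object (or compatible list).
#' @param par Irradiance (PAR), umol photon m^-2 s^-1; finite, >= 0. May be a
#'   vector.
#' @return Net assimilation rate(s), umol CO2 m^-2 s^-1.
#' @export
#' @examples
#' p <- lrc_params(20, 0.05, 1.5, 0.8)
#' nrh_mean(p, 0)     # equals -r_d at darkness
#' nrh_mean(p, 1e6)   # approaches a_max - r_d
nrh_mean <- function(params, par) {
  viol <- validate_params(params)
  if (length(viol)) stop("invalid params: ", paste(viol, collapse = "; "))
  if (!is.numeric(par) || any(!is.finite(par)) || any(par < 0)) {
    stop("par must be finite and >= 0")
  }
  .nrh(params$a_max, params$alpha, params$r_d, params$theta, par)
}

#' Rectangular-hyperbola limit of the light response model
#'
#' The theta -> 0 limit of [nrh_mean()]:
#' \eqn{\mu(I) = \alpha I A_{max} / (\alpha I + A_{max}) - R_d}.
#' `theta` in `params` is ignored.
#'
#' @inheritParams nrh_mean
#' @return Net assimilation rate(s), umol CO2 m^-2 s^-1.
#' @export
nrh_mean_theta_zero <- function(params, par) {
  if (!is.numeric(par) || any(!is.finite(par)) || any(par < 0)) {
    stop("par must be finite and >= 0")
  }
  if (params$a_max <= 0 || params$alpha <= 0) {
    stop("a_max and alpha must be > 0")
  }
  denom <- params$alpha * par + params$a_max
  if (any(denom == 0)) stop("alpha*par + a_max must be nonzero")
  params$alpha * par * params$a_max / denom - params$r_d
}
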