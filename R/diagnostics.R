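#' Brooks-Gelman-Rubin convergence diagnostic (potential scale reduction)
#'
#' Classic Gelman-Rubin PSRF per scalar parameter: with `m` chains of `n`
#' draws, `W` is the mean within-chain variance, `B/n` the variance of the
#' chain means, `Vhat = ((n-1)/n) W + B/n`, and `PSRF = sqrt(Vhat / W)`.
#' Parameters with zero within-chain variance (e.g. held fixed) are reported
#' as degenerate, not failed. The fit is flagged converged iff every
#' non-degenerate PSRF is below `threshold`.
#'
#' @param draws An `lrc_draws` object, a matrix with one column per chain, or
#'   a list of equal-length chain vectors (for a single parameter).
#' @param threshold PSRF convergence threshold (default 1.1).
#' @return Object of class `lrc_convergence`: a data.frame with columns
#'   `parameter`, `psrf`, `degenerate`, `converged`, with the threshold and
#'   an overall `converged` flag as attributes.
#' @export
#' @examples
#' bgr_diagnostic(cbind(c(1, 2, 3), c(1, 2, 3)))  # identical chains
bgr_diagnostic <- function(draws, threshold = 1.1) {
  UseMethod("bgr_diagnostic")
}

#' @export
bgr_diagnostic.list <- function(draws, threshold = 1.1) {
  bgr_diagnostic(do.call(cbind, draws), threshold = threshold)
}

#' @export
bgr_diagnostic.matrix <- function(draws, threshold = 1.1) {
  arr <- array(t(draws), dim = c(ncol(draws), nrow(draws), 1),
               dimnames = list(NULL, NULL, "x"))
  .bgr_core(arr, threshold)
}

#' @export
bgr_diagnostic.lrc_draws <- function(draws, threshold = 1.1) {
  .bgr_core(draws$draws, threshold)
}

# arr: chains x iterations x parameters
.bgr_core <- function(arr, threshold) {
  m <- dim(arr)[1]; n <- dim(arr)[2]; npar <- dim(arr)[3]
  if (m < 2) stop("BGR diagnostic requires at least 2 chains")
  if (n < 2) stop("BGR diagnostic requires at least 2 draws per chain")
  psrf <- rep(NA_real_, npar)
  degen <- rep(FALSE, npar)
  for (j in seq_len(npar)) {
    x <- arr[, , j, drop = FALSE]
    dim(x) <- c(m, n)
    w_j <- apply(x, 1, var)
    W <- mean(w_j)
    if (W == 0) { degen[j] <- TRUE; next }
    B_over_n <- var(rowMeans(x))
    Vhat <- (n - 1) / n * W + B_over_n
    psrf[j] <- sqrt(Vhat / W)
  }
  pn <- dimnames(arr)[[3]]
  if (is.null(pn)) pn <- paste0("par", seq_len(npar))
  rep_df <- data.frame(parameter = pn, psrf = psrf, degenerate = degen,
                       converged = !degen & !is.na(psrf) & psrf < threshold,
                       stringsAsFactors = FALSE)
  structure(rep_df, class = c("lrc_convergence", "data.frame"),
            threshold = threshold,
            converged = all(rep_df$converged | rep_df$degenerate))
}

#' @export
print.lrc_convergence <- function(x, ...) {
  ok <- attr(x, "converged")
  cat(sprintf("BGR convergence report: %d parameters, threshold %.3g, %s\n",
              nrow(x), attr(x, "threshold"),
              if (ok) "all converged" else "NOT converged"))
  worst <- x[order(-x$psrf), ][seq_len(min(5, sum(!x$degenerate))), ]
  print.data.frame(worst, row.names = FALSE)
  invisible(x)
}

#' Thin retained posterior draws
#'
#' Keeps the first draw and every `k`-th draw thereafter in each chain
#' (iterations 1, 1+k, 1+2k, ...), updating the stored thinning metadata.
#'
#' @param draws An `lrc_draws` object.
#' @param k Keep-every interval; >= 1 and at most the chain length.
#' @return The thinned `lrc_draws`.
#' @export
thin_draws <- function(draws, k) {
  stopifnot(inherits(draws, "lrc_draws"))
  n <- dim(draws$draws)[2]
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of retained draws per chain (", n, ")")
  keep <- seq(1L, n, by = as.integer(k))
  draws$draws <- draws$draws[, keep, , drop = FALSE]
  draws$config$n_iter <- length(keep)
  draws$config$thin <- draws$config$thin * as.integer(k)
  draws
}

#' Per-observation posterior predictive distribution
#'
#' For every observation and every retained draw, simulates a replicate
#' measurement from the likelihood (normal around the draw's plant-level
#' curve mean, sd `1/sqrt(tau_obs)`), and summarises the replicates by their
#' mean and empirical 2.5%/97.5% quantiles (type 7).
#'
#' @param draws An `lrc_draws` object fitted to data sharing plant labels
#'   with `data`.
#' @param data The observed dataset.
#' @return Object of class `lrc_ppd`: data.frame with columns `obs_id`,
#'   `mean`, `lower`, `upper` (2.5% and 97.5% bounds).
#' @export
posterior_predictive <- function(draws, data) {
  stopifnot(inherits(draws, "lrc_draws"))
  data <- validate_dataset(data)
  missing_p <- setdiff(unique(data$plant), draws$plant_labs)
  if (length(missing_p)) {
    stop("plant(s) in data without posterior draws: ",
         paste(missing_p, collapse = ", "))
  }
  pm <- posterior_matrix(draws)
  D <- nrow(pm)
  sd_o <- 1 / sqrt(pm[, "tau_obs"])
  n <- nrow(data)
  mean_v <- lower_v <- upper_v <- numeric(n)
  for (pl in unique(data$plant)) {
    rows <- which(data$plant == pl)
    am <- pm[, paste0("a_max[", pl, "]")]
    al <- pm[, paste0("alpha[", pl, "]")]
    rd <- pm[, paste0("r_d[", pl, "]")]
    th <- pm[, paste0("theta[", pl, "]")]
    for (i in rows) {
      mu_d <- .nrh(am, al, rd, th, data$PARi[i])
      yrep <- mu_d + rnorm(D, 0, sd_o)
      mean_v[i] <- mean(yrep)
      qs <- quantile(yrep, c(0.025, 0.975), names = FALSE, type = 7)
      lower_v[i] <- qs[1]; upper_v[i] <- qs[2]
    }
  }
  structure(data.frame(obs_id = data$obs_id, mean = mean_v,
                       lower = lower_v, upper = upper_v),
            class = c("lrc_ppd", "data.frame"))
}

#' Observed-versus-predicted goodness of fit
#'
#' Ordinary least squares of the posterior predictive means on the observed
#' values (predicted regressed on observed, recorded in the output), with
#' R-squared as the squared Pearson correlation. R-squared is signless; the
#' slope carries the direction.
#'
#' @param observed Numeric vector of observed values (length >= 3, nonzero
#'   variance).
#' @param predictive An `lrc_ppd` object or a numeric vector of predicted
#'   means of the same length.
#' @return Object of class `lrc_gof`: list with `r_squared`, `slope`,
#'   `intercept`, `n`, and `orientation = "predicted_on_observed"`.
#' @export
goodness_of_fit <- function(observed, predictive) {
  pred <- if (inherits(predictive, "lrc_ppd")) predictive$mean else predictive
  if (!is.numeric(pred)) stop("predictive must be numeric or an lrc_ppd")
  if (length(observed) != length(pred)) stop("lengths differ")
  if (length(observed) < 3) stop("need at least 3 points")
  if (sd(observed) == 0 || sd(pred) == 0) {
    stop("zero variance in observed or predicted values: fit undefined")
  }
  fit <- lm(pred ~ observed)
  structure(list(r_squared = unname(cor(observed, pred)^2),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = length(observed),
                 orientation = "predicted_on_observed"),
            class = "lrc_gof")
}

#' @export
print.lrc_gof <- function(x, ...) {
  cat(sprintf("Goodness of fit (predicted on observed, n = %d):\n", x$n))
  cat(sprintf("  R^2 = %.4f, slope = %.4f, intercept = %.4f\n",
              x$r_squared, x$slope, x$intercept))
  invisible(x)
}
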