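# Truncated-normal helpers. Densities keep the normalising constant exactly:
# the genotype mean and precision conditionals depend on it.

# log density of N(mean, sd) truncated to [lo, up]; -Inf outside.
# All arguments recycle.
.dtnorm_log <- function(x, mean, sd, lo, up) {
  out <- dnorm(x, mean, sd, log = TRUE) - .ltnz(mean, sd, lo, up)
  out[x < lo | x > up] <- -Inf
  out
}

# log truncation normaliser log(Phi(up) - Phi(lo)), underflow-guarded
.ltnz <- function(mean, sd, lo, up) {
  z <- pnorm(up, mean, sd) - pnorm(lo, mean, sd)
  if (any(small <- z < 1e-300)) z[small] <- 1e-300
  log(z)
}

# Rejection sampler for N(mean, sd) truncated to [lo, up]; exact. mean may be
# a vector; sd scalar or vector. sd = 0 degenerates to the mean (which must
# lie inside the bounds).
.rtnorm <- function(n, mean, sd, lo, up, max_tries = 1000L) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- mean
  if (all(sd == 0)) {
    if (any(mean < lo | mean > up)) {
      stop("degenerate truncated normal: mean outside truncation bounds")
    }
    return(out)
  }
  need <- rep(TRUE, n)
  for (i in seq_len(max_tries)) {
    k <- sum(need)
    if (k == 0L) break
    draw <- rnorm(k, mean[need], sd[need])
    ok <- draw >= lo & draw <= up
    idx <- which(need)[ok]
    out[idx] <- draw[ok]
    need[idx] <- FALSE
    if (!any(need)) break
  }
  if (any(need)) {
    stop("truncated-normal rejection sampling failed after ", max_tries,
         " attempts: hyperparameters incompatible with parameter constraints")
  }
  out
}
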