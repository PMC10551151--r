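#' Random subsample of pooled posterior draws for one parameter
#'
#' Draws `n` values uniformly without replacement from the pooled chains.
#' A small fixed-size subsample (default 50) is used for the frequentist
#' comparisons so that the enormous pooled posterior sample size does not by
#' itself drive p-values toward zero.
#'
#' @param draws An `lrc_draws` object or a numeric vector of pooled draws.
#' @param parameter Parameter name (e.g. `"mu_a_max[G1]"`); ignored when
#'   `draws` is already a numeric vector.
#' @param n Subsample size; must not exceed the pooled draw count.
#' @return Numeric vector of length `n`.
#' @export
subsample_posterior <- function(draws, parameter = NULL, n = 50) {
  pooled <- if (is.numeric(draws)) {
    draws
  } else {
    stopifnot(inherits(draws, "lrc_draws"))
    if (is.null(parameter)) stop("parameter must be given for lrc_draws input")
    if (!parameter %in% draws$par_names) stop("unknown parameter: ", parameter)
    as.vector(draws$draws[, , parameter])
  }
  if (n > length(pooled)) {
    stop("subsample size ", n, " exceeds available draws (", length(pooled), ")")
  }
  pooled[sample.int(length(pooled), n)]
}

#' One-way ANOVA across groups of values
#'
#' Standard one-way fixed-effects ANOVA (computed via [stats::aov()]) with F
#' on (g-1, N-g) degrees of freedom. The degenerate case of zero pooled
#' within-group variance with nonzero between-group variance is reported as
#' `F = Inf`, `p = 0` and flagged.
#'
#' @param groups List (optionally named) of >= 2 numeric vectors, each of
#'   length >= 2.
#' @return List with `f`, `p`, `df` (numerator, denominator) and `degenerate`.
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))
anova_oneway <- function(groups) {
  .check_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ssw <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - mean(y))^2)
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  if (ssw == 0 && ssb > 0) {
    return(list(f = Inf, p = 0, df = c(df1, df2), degenerate = TRUE))
  }
  tab <- anova(aov(y ~ g))
  list(f = unname(tab$`F value`[1]), p = unname(tab$`Pr(>F)`[1]),
       df = c(df1, df2), degenerate = FALSE)
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  if (!all(vapply(groups, is.numeric, TRUE))) stop("groups must be numeric")
  invisible(groups)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences with studentized-range adjusted p-values
#' (computed via [stats::TukeyHSD()]); a pair is significant iff its adjusted
#' p-value is below `alpha`. With zero within-group variance and separated
#' means the adjusted p is reported as 0 and the table flagged degenerate.
#'
#' @inheritParams anova_oneway
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per pair (`C(g,2)` rows): `pair`, `diff`,
#'   `lower`, `upper`, `p_adj`, `significant`; attribute `degenerate`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  .check_groups(groups)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  ssw <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  degenerate <- FALSE
  if (ssw == 0) {
    degenerate <- TRUE
    cmb <- utils::combn(names(groups), 2)
    d <- vapply(seq_len(ncol(cmb)),
                function(j) mean(groups[[cmb[2, j]]]) - mean(groups[[cmb[1, j]]]), 0)
    out <- data.frame(pair = paste(cmb[2, ], cmb[1, ], sep = "-"),
                      diff = d, lower = d, upper = d,
                      p_adj = ifelse(d == 0, 1, 0),
                      significant = d != 0, stringsAsFactors = FALSE)
  } else {
    tk <- TukeyHSD(aov(y ~ g))$g
    out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lower = tk[, "lwr"], upper = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "degenerate") <- degenerate
  attr(out, "alpha") <- alpha
  out
}

#' Compare one parameter's posterior across fits
#'
#' The hypothesis-testing procedure applied after fitting the model
#' separately per group (environment, measurement method, or genotype):
#' a fixed-size random subsample is taken from each fit's pooled posterior
#' for the chosen parameter, then one-way ANOVA and Tukey HSD pairwise
#' comparisons are run over the subsamples. Treating posterior draws as data
#' points for frequentist tests is statistically unorthodox; the result
#' carries a note flagging that interpretation caveat.
#'
#' @param fits Named list (>= 2) of `lrc_draws` objects or numeric vectors of
#'   pooled draws, one per group.
#' @param parameter Parameter name to extract from `lrc_draws` entries
#'   (e.g. `"mu_a_max[G1]"`); may be a single name or one name per fit (when
#'   the same quantity has different labels across fits).
#' @param factor_name Label for the grouping factor (e.g. `"environment"`).
#' @param n Subsample size per group (default 50).
#' @param alpha Significance level for the Tukey flags.
#' @return Object of class `lrc_comparison`: parameter, factor, subsample
#'   size, `anova` (f, p, df, degenerate), `tukey` table, and `note`.
#' @export
compare_parameters <- function(fits, parameter = NULL,
                               factor_name = "group", n = 50, alpha = 0.05) {
  if (!is.list(fits) || length(fits) < 2) stop("need at least 2 fits")
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("fit", seq_along(fits))
  }
  pars <- if (is.null(parameter)) rep(list(NULL), length(fits)) else
    as.list(rep_len(parameter, length(fits)))
  groups <- lapply(seq_along(fits), function(i) {
    subsample_posterior(fits[[i]], pars[[i]], n = n)
  })
  names(groups) <- names(fits)
  an <- anova_oneway(groups)
  tk <- tukey_hsd(groups, alpha = alpha)
  structure(list(parameter = if (is.null(parameter)) NA_character_ else
                   paste(unique(unlist(parameter)), collapse = ","),
                 factor = factor_name, n = n, alpha = alpha,
                 anova = an, tukey = tk,
                 note = paste("posterior draws treated as data points for",
                              "frequentist tests; p-values are descriptive,",
                              "not calibrated error rates")),
            class = "lrc_comparison")
}

#' @export
print.lrc_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %s across %s (subsample n = %d per group)\n",
              x$parameter, x$factor, x$n))
  cat(sprintf("  ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$anova$df[1], x$anova$df[2], x$anova$f, x$anova$p,
              if (x$anova$degenerate) " [degenerate]" else ""))
  print.data.frame(x$tukey, row.names = FALSE, digits = 4)
  cat("  note:", x$note, "\n")
  invisible(x)
}
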