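#' Read a gas-exchange CSV file
#'
#' Parses a tabular gas-exchange file into the dataset contract used by the
#' fitting functions. Mandatory columns: `genotype`, `plant`, PAR (named
#' `PARi` or `PAR`) and net photosynthesis (named `A`, `Photo` or `A_N`);
#' optional: `obs_id`, `environment`, `Tair`, `VPD`. Rows violating the
#' observation invariants (negative or non-finite PAR, non-finite A, empty
#' labels) are rejected with a warning naming their line numbers; the valid
#' rows are kept.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated data.frame with columns `obs_id`, `genotype`, `plant`,
#'   `environment`, `PARi`, `A` and, when present, `Tair`, `VPD`.
#' @export
read_gas_exchange_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  par_col <- intersect(c("PARi", "PAR"), names(raw))[1]
  a_col <- intersect(c("A", "Photo", "A_N"), names(raw))[1]
  miss <- c(if (!"genotype" %in% names(raw)) "genotype",
            if (!"plant" %in% names(raw)) "plant",
            if (is.na(par_col)) "PARi/PAR",
            if (is.na(a_col)) "A/Photo/A_N")
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.frame(
    obs_id = if ("obs_id" %in% names(raw)) raw$obs_id else seq_len(nrow(raw)),
    genotype = as.character(raw$genotype),
    plant = as.character(raw$plant),
    environment = if ("environment" %in% names(raw))
      as.character(raw$environment) else "unknown",
    PARi = suppressWarnings(as.numeric(raw[[par_col]])),
    A = suppressWarnings(as.numeric(raw[[a_col]])),
    stringsAsFactors = FALSE
  )
  if ("Tair" %in% names(raw)) out$Tair <- suppressWarnings(as.numeric(raw$Tair))
  if ("VPD" %in% names(raw)) out$VPD <- suppressWarnings(as.numeric(raw$VPD))
  bad <- !is.finite(out$PARi) | out$PARi < 0 | !is.finite(out$A) |
    !nzchar(out$genotype) | !nzchar(out$plant) | is.na(out$genotype) |
    is.na(out$plant)
  if (any(bad)) {
    warning("rejected ", sum(bad), " invalid row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  validate_dataset(out)
}

#' Write a gas-exchange dataset to CSV
#'
#' Columns are written in the instrument-style order `obs_id`, `genotype`,
#' `plant`, `environment`, `PARi`, `A`, `Tair`, `VPD`; a round trip through
#' [read_gas_exchange_csv()] reproduces the dataset.
#'
#' @param data A dataset accepted by [validate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange_csv <- function(data, path) {
  data <- validate_dataset(data)
  if (is.null(data$Tair)) data$Tair <- NA_real_
  if (is.null(data$VPD)) data$VPD <- NA_real_
  cols <- c("obs_id", "genotype", "plant", "environment", "PARi", "A",
            "Tair", "VPD")
  write.csv(data[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Persist posterior draws as CSV with a JSON metadata sidecar
#'
#' One row per retained draw: `chain`, `iteration`, then one column per named
#' parameter. The sidecar (same path with `.json` appended) records the seed,
#' sampler configuration and priors.
#'
#' @param draws An `lrc_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "lrc_draws"))
  d <- dim(draws$draws)
  tab <- data.frame(chain = rep(seq_len(d[1]), each = d[2]),
                    iteration = rep(seq_len(d[2]), times = d[1]))
  flat <- matrix(aperm(draws$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(flat) <- draws$par_names
  write.csv(cbind(tab, flat), path, row.names = FALSE)
  meta <- list(seed = draws$config$seed,
               n_chains = draws$config$n_chains,
               n_adapt = draws$config$n_adapt,
               n_iter = draws$config$n_iter,
               thin = draws$config$thin,
               priors = list(mean = as.list(draws$priors$mean),
                             sd = as.list(draws$priors$sd),
                             lower = as.list(draws$priors$lower),
                             upper = as.list(draws$priors$upper),
                             prec_shape = draws$priors$prec_shape,
                             prec_rate = draws$priors$prec_rate),
               plants = draws$plant_labs, genotypes = draws$geno_labs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Configuration for the end-to-end analysis pipeline
#'
#' @param output_dir Directory for all artifacts (created if absent).
#' @param environments Named list, one entry per growing environment; each
#'   entry is a list with exactly one of `data` (path to a gas-exchange CSV)
#'   or `sim` (an [sim_config()] whose seed the pipeline re-derives from the
#'   global seed).
#' @param priors An [prior_spec()].
#' @param fit An [fit_config()]; its seed is re-derived per environment from
#'   the global seed.
#' @param compare List: `parameters` (curve parameters to compare), `n`
#'   (subsample size) and `alpha`.
#' @param seed Global integer seed; every stage's RNG stream derives from it.
#' @param psrf_threshold BGR convergence threshold; the pipeline aborts if a
#'   fit fails it.
#' @param post_thin Additional post-hoc thinning applied after fitting.
#' @return Object of class `lrc_run_config`.
#' @export
pipeline_config <- function(output_dir, environments,
                            priors = prior_spec(), fit = fit_config(),
                            compare = list(parameters = c("a_max", "alpha",
                                                          "r_d", "theta"),
                                           n = 50, alpha = 0.05),
                            seed = 1L, psrf_threshold = 1.1, post_thin = 1L) {
  if (!is.list(environments) || is.null(names(environments)) ||
      any(!nzchar(names(environments)))) {
    stop("environments must be a named list")
  }
  for (nm in names(environments)) {
    e <- environments[[nm]]
    has <- c(!is.null(e$data), !is.null(e$sim))
    if (sum(has) != 1L) {
      stop("environment '", nm, "' must provide exactly one of data or sim")
    }
  }
  structure(list(output_dir = output_dir, environments = environments,
                 priors = priors, fit = fit, compare = compare,
                 seed = as.integer(seed), psrf_threshold = psrf_threshold,
                 post_thin = as.integer(post_thin)),
            class = "lrc_run_config")
}

# Small derived-seed helper; keeps values inside 32-bit integer range.
.derive_seed <- function(seed, stage, i = 0L) {
  (as.integer(seed) * 97L + stage * 7919L + i * 131L) %% 2147483629L
}

#' Run the full multi-environment analysis pipeline
#'
#' For each configured environment: obtain the dataset (read or simulate),
#' fit the hierarchical model, check BGR convergence (aborting with a
#' diagnostic if unconverged), optionally thin, compute per-observation
#' posterior predictive intervals and the observed-versus-predicted goodness
#' of fit, and persist all artifacts as CSV/JSON. Afterwards, the chosen
#' curve parameters are compared across environments (per shared genotype)
#' and across genotypes (within each environment) by subsampled ANOVA +
#' Tukey HSD. A manifest listing every output file with its MD5 checksum is
#' written last. All randomness derives from the global seed; progress is
#' logged to stderr, never mixed into numeric outputs.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list with the fits, goodness-of-fit summaries,
#'   comparison tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lrc_run_config"))
  t0 <- Sys.time()
  log_msg <- function(...) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_files <- character(0)
  emit <- function(writer, obj, name) {
    p <- file.path(config$output_dir, name)
    writer(obj, p)
    out_files <<- c(out_files, p)
    p
  }
  fits <- list(); gofs <- list(); datasets <- list()
  env_names <- names(config$environments)
  for (i in seq_along(env_names)) {
    nm <- env_names[i]
    e <- config$environments[[nm]]
    log_msg("[data:", nm, "] preparing dataset")
    data <- tryCatch({
      if (!is.null(e$data)) {
        read_gas_exchange_csv(e$data)
      } else {
        sc <- e$sim
        sc$seed <- .derive_seed(config$seed, 1L, i)
        sc$environment <- nm
        simulate_dataset(sc)$data
      }
    }, error = function(err) stop("[data:", nm, "] ", conditionMessage(err),
                                  call. = FALSE))
    datasets[[nm]] <- data
    emit(write_gas_exchange_csv, data, paste0(nm, "_data.csv"))

    log_msg("[fit:", nm, "] sampling (", nrow(data), " observations)")
    fc <- config$fit
    fc$seed <- .derive_seed(config$seed, 2L, i)
    fit <- tryCatch(fit_lrc(data, config$priors, fc),
                    error = function(err) stop("[fit:", nm, "] ",
                                               conditionMessage(err),
                                               call. = FALSE))
    conv <- bgr_diagnostic(fit, threshold = config$psrf_threshold)
    emit(function(o, p) write.csv(as.data.frame(o), p, row.names = FALSE),
         conv, paste0(nm, "_convergence.csv"))
    if (!attr(conv, "converged")) {
      worst <- conv[which.max(conv$psrf), ]
      stop("[bgr:", nm, "] chains not converged: worst PSRF ",
           sprintf("%.3f", worst$psrf), " (", worst$parameter,
           ") above threshold ", config$psrf_threshold, call. = FALSE)
    }
    if (config$post_thin > 1L) fit <- thin_draws(fit, config$post_thin)
    fits[[nm]] <- fit
    emit(write_draws_csv, fit, paste0(nm, "_draws.csv"))
    out_files <- c(out_files,
                   file.path(config$output_dir, paste0(nm, "_draws.csv.json")))

    log_msg("[evaluate:", nm, "] posterior predictive + goodness of fit")
    set.seed(.derive_seed(config$seed, 3L, i))
    ppd <- posterior_predictive(fit, data)
    emit(function(o, p) write.csv(as.data.frame(o), p, row.names = FALSE),
         ppd, paste0(nm, "_posterior_predictive.csv"))
    gof <- goodness_of_fit(data$A, ppd)
    gofs[[nm]] <- gof
    emit(function(o, p) jsonlite::write_json(unclass(o), p, auto_unbox = TRUE,
                                             digits = NA),
         gof, paste0(nm, "_gof.json"))
  }

  log_msg("[compare] cross-environment and cross-genotype comparisons")
  comp_rows <- list()
  cmp_i <- 0L
  add_cmp <- function(res, scope, group_label) {
    tk <- res$tukey
    data.frame(scope = scope, group = group_label, parameter = res$parameter,
               f = res$anova$f, p_anova = res$anova$p, pair = tk$pair,
               diff = tk$diff, p_adj = tk$p_adj,
               significant = tk$significant, stringsAsFactors = FALSE)
  }
  for (par in config$compare$parameters) {
    # across environments, per genotype present in >= 2 environments
    geno_by_env <- lapply(fits, function(f) f$geno_labs)
    all_genos <- unique(unlist(geno_by_env))
    for (g in all_genos) {
      envs_with <- env_names[vapply(env_names,
                                    function(nm) g %in% fits[[nm]]$geno_labs,
                                    TRUE)]
      if (length(envs_with) < 2) next
      cmp_i <- cmp_i + 1L
      set.seed(.derive_seed(config$seed, 4L, cmp_i))
      res <- compare_parameters(
        setNames(lapply(envs_with, function(nm) fits[[nm]]), envs_with),
        parameter = paste0("mu_", par, "[", g, "]"),
        factor_name = "environment",
        n = config$compare$n, alpha = config$compare$alpha)
      comp_rows[[length(comp_rows) + 1L]] <-
        add_cmp(res, "across_environments", g)
    }
    # across genotypes, within each environment
    for (nm in env_names) {
      f <- fits[[nm]]
      if (length(f$geno_labs) < 2) next
      cmp_i <- cmp_i + 1L
      set.seed(.derive_seed(config$seed, 5L, cmp_i))
      groups <- setNames(
        lapply(f$geno_labs, function(g)
          as.vector(f$draws[, , paste0("mu_", par, "[", g, "]")])),
        f$geno_labs)
      res <- compare_parameters(groups, factor_name = "genotype",
                                n = config$compare$n,
                                alpha = config$compare$alpha)
      res$parameter <- par
      comp_rows[[length(comp_rows) + 1L]] <- add_cmp(res, "across_genotypes", nm)
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame()
  cp <- file.path(config$output_dir, "comparisons.csv")
  write.csv(comparisons, cp, row.names = FALSE)
  out_files <- c(out_files, cp)

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("lrcbayes")),
    psrf_threshold = config$psrf_threshold,
    environments = env_names,
    note = "comparisons treat posterior draws as data points (descriptive p-values)",
    files = lapply(sort(unique(out_files)), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  mp <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  log_msg("[done] ", length(out_files) + 1L, " artifacts in ",
          config$output_dir, " (",
          sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))),
          " s)")
  invisible(list(fits = fits, gof = gofs, comparisons = comparisons,
                 manifest = manifest, datasets = datasets))
}
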