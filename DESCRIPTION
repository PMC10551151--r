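Package: lrcbayes
Title: Hierarchical Bayesian Analysis of Photosynthesis Light Response Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the non-rectangular hyperbola light response model to leaf
    gas-exchange measurements in a multilevel Bayesian framework: plant-level
    curve parameters (Amax, alpha, Rd, theta) nested within genotype-level
    means, sampled by an adaptive Metropolis-within-Gibbs MCMC. Includes a
    synthetic-data generator for sequential and non-sequential (survey)
    measurement designs, Brooks-Gelman-Rubin convergence diagnostics,
    per-observation posterior predictive intervals with goodness-of-fit
    summaries, a brute-force grid-posterior oracle for sampler validation,
    and ANOVA with Tukey HSD comparisons of parameter posteriors across
    genotypes and growing environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
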