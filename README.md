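# lrcbayes

Hierarchical Bayesian estimation of photosynthesis light-response parameters
from leaf gas-exchange data.

## The problem

Plant phenotyping programmes characterise genotypes by their light response:
net CO2 assimilation `A_N` (µmol CO2 m⁻² s⁻¹) measured against irradiance
`PAR` (µmol photon m⁻² s⁻¹), either by stepping one leaf through a ladder of
chamber light levels (the *sequential* method) or by pooling measurements
from many samples each acclimated to its ambient light (the *non-sequential*
or survey method). Fitting each curve in isolation wastes the structure of
such experiments — several replicate plants per genotype, several genotypes
per growing environment — and gives no honest uncertainty on genotype-level
parameters. `lrcbayes` fits all curves of an environment at once in a
multilevel Bayesian model and provides the downstream machinery used in this
kind of study: convergence diagnostics, per-observation posterior predictive
intervals, goodness of fit, and ANOVA/Tukey comparisons of parameter
posteriors across genotypes and environments.

## The model

The mean response is the non-rectangular hyperbola

```
mu(I) = [ alpha*I + Amax - sqrt((alpha*I + Amax)^2 - 4*theta*alpha*I*Amax) ] / (2*theta) - Rd
```

with `Amax` the light-saturated gross assimilation, `alpha` the apparent
quantum yield (initial slope), `Rd` mitochondrial respiration and
`theta` in (0, 1] the curvature (`theta -> 0`: rectangular hyperbola;
`theta = 1`: Blackman response). Observations are Gaussian around `mu` with
precision `tau`; each plant carries its own four parameters, drawn from
truncated normals around genotype-level means; genotype means carry weak
truncated-normal priors (sd = 2 × mean) centred on values typical for rice,
and precisions carry Gamma(0.01, 0.01). The joint posterior is sampled by an
adaptive Metropolis-within-Gibbs MCMC (3 chains × 10,000 retained draws,
thinned every 10th, in the reference protocol), checked with the
Brooks–Gelman–Rubin diagnostic, and validated against a brute-force grid
posterior on a reduced model.

## Worked example

```r
library(lrcbayes)

# two genotypes x three replicate plants stepped through an 11-level light
# ladder (2000 ... 50, plus darkness), with known ground truth
sim <- simulate_dataset(sim_config(
  n_genotypes = 2, n_replicates = 3,
  design = design_sequential(c(light_ladder_growth_chamber(), 0)),
  environment = "growth_chamber", noise_sd = 0.5, seed = 7))

fit <- fit_lrc(sim$data,
               config = fit_config(n_chains = 3, n_adapt = 3000,
                                   n_iter = 1000, thin = 10, seed = 7))
bgr_diagnostic(fit)

set.seed(7)
gof <- goodness_of_fit(sim$data$A, posterior_predictive(fit, sim$data))
gof

pm <- posterior_matrix(fit)
round(c(estimate = mean(pm[, "mu_a_max[G1]"]),
        truth = sim$truth$genotype_means["G1", "a_max"]), 5)
```

Output from this exact script:

```
BGR convergence report: 37 parameters, threshold 1.1, all converged
    parameter     psrf degenerate converged
 mu_theta[G1] 1.049778      FALSE      TRUE
 mu_theta[G2] 1.045482      FALSE      TRUE
    tau_theta 1.042194      FALSE      TRUE
   r_d[G2.P3] 1.004151      FALSE      TRUE
 a_max[G2.P2] 1.004106      FALSE      TRUE
Goodness of fit (predicted on observed, n = 66):
  R^2 = 0.9989, slope = 0.9985, intercept = 0.0247
estimate    truth
33.35729 31.86174
```

Reading it: all potential scale reduction factors sit below the 1.1
threshold, so the three chains agree; the posterior predictive means track
the 66 observations almost perfectly (R² = 0.999 at observation noise
sd 0.5); and the genotype-level `Amax` posterior mean lands within ~5% of
the generating value — `Amax` is the hardest parameter of the four, since
it trades off against the curvature `theta` unless the ladder reaches
saturating light. `compare_parameters()` then takes named fits (or pooled
draw vectors), subsamples 50 draws per group and reports ANOVA F/p plus a
Tukey HSD table; `run_pipeline()` chains the whole multi-environment
workflow and writes CSV/JSON artifacts with a checksummed manifest (see
`inst/cli/lrc_pipeline.R` for the shell entry point).

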