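# urbanocc

Multi-species occupancy and pollinator richness models for urban
greenspaces.

## What this package is for

Urban greenspace managers want to know which features of a site — its own
vegetation, the surrounding neighborhood, or its position relative to
regional water features — matter most for biodiversity, and in which
seasons. `urbanocc` implements the statistical core of such an analysis
for two taxa:

- **Birds**, through seasonal hierarchical Bayesian **multi-species
  occupancy models** on robust-design detection histories (sites visited
  repeatedly within a season; visits grouped into primary periods of
  adjacent secondary occasions), correcting species richness for imperfect
  detection;
- **Pollinators**, through **Poisson log-linear regression** of pooled
  taxonomic richness on the same site covariates, with an overdispersion
  check.

It is aimed at quantitative ecologists who have detection-history,
covariate and count tables and want the full pipeline: data validation and
standardization, exact-posterior Gibbs sampling, richness predictions at
hypothetical "good" and "poor" sites, urban-tolerance subsetting,
posterior predictive checks, and residual spatial-autocorrelation
diagnostics. A synthetic-data generator reproduces the generative process
end to end, so every stage is testable without field data.

## The model

For species *i*, site *j*, primary period *k*, secondary occasion *t*:

    z_ijk  | psi_ijk   ~ Bernoulli(psi_ijk)          latent incidence
    y_ijkt | z_ijk, p  ~ Bernoulli(z_ijk * p_ijkt)   detection

    logit(psi_ijk) = alpha0_i + alpha_i' X_j
    logit(p_ijkt)  = beta0_ik + beta_i' X_jkt

Species coefficients are exchangeable draws from community normal
distributions; community means have Normal(0, sigma^2 = 2.72) priors
(near-uniform on the probability scale) and community variances
InvGamma(0.1, 0.1). Fitting uses a Pólya-Gamma augmented Gibbs sampler
(exact conditionals throughout, written in C++ for this package), with
defaults of 3 chains × 54,000 iterations, 10,000 burn-in, thinning 10
(13,200 retained draws) and Gelman-Rubin R-hat < 1.1 as the convergence
rule. Richness for any species subset is the sum of the latent incidence
matrix, draw by draw. Details, assumptions and numerical choices are in
the vignette (`vignettes/urbanocc-methods.Rmd`).

## Worked example

Simulate a community under the default study conditions (45 sites, 3 × 3
robust design, 35–44 sites surveyed), fit one season, and derive
quantities:

```r
library(urbanocc)

cfg <- generator_config(n_species = 40, seed = 11)
sim <- simulate_dataset(cfg)

fit <- fit_msom(sim$detections$spring, sim$covariates,
                config = mcmc_config(3, 6000, 1000, 5, seed = 3))

# goodness of fit and convergence
ppc_chisq(fit, seed = 1)$p_value
max(fit$rhat)

# richness at a hypothetical best-quality site vs the poorest
sc <- build_scenarios(sim$covariates)
X <- attr(sc, "x")
best  <- richness_posterior(predict_incidence(fit, X["good_good_good", ,
                                                     drop = FALSE],
                                              seed = 2))
worst <- richness_posterior(predict_incidence(fit, X["poor_poor_poor", ,
                                                     drop = FALSE],
                                              seed = 2))
best
worst

# species gained per +10 percentage points of local canopy cover
richness_delta(fit, "canopy_local", delta_raw = 10)$mean
```

Output (seeds as above):

```
[1] 0.4973333                # PPC Bayesian p-value: no sign of misfit
[1] 1.101                    # worst R-hat across all parameters
Richness posterior over 40 species: mean 36.1, 95% HDI 32.0-39.0
Richness posterior over 40 species: mean 6.6, 95% HDI 2.0-11.0
[1] 2.544764                 # species gained per +10% canopy
```

The first two numbers say the model reproduces its own data (a Bayesian
p-value near 0.5) and the chains just reach the R-hat 1.1 rule at this
reduced run length (use the 54,000-iteration defaults for production
fits). The richness posteriors say a site with the best observed
conditions at all three spatial scales is expected to host about five
times as many of the modeled species as one with the poorest conditions,
with 95% highest-density intervals attached; the final number is the
expected gain in species for a 10-percentage-point increase in local
canopy cover at an otherwise average site.

The pollinator side:

```r
poll <- sim$pollinators[sim$pollinators$season == "early_summer", ]
gf <- fit_pollinator_glm(poll)
gf$coefficients[gf$coefficients$term == "dist_bay_km", ]
dispersion_check(gf)
```

```
          term estimate     se ci_low ci_high significant
10 dist_bay_km   -0.311 0.0978 -0.503  -0.119        TRUE
$phi
[1] 0.9491894
$verdict
[1] "ok"
```

Pollinator richness declines with distance from the bay (the generative
effect is −0.4 on the log scale; the fit recovers −0.31 ± 0.10), and the
Pearson dispersion statistic near 1 shows no overdispersion.

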