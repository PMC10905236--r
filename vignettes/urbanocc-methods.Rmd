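---
title: "Models and methods in urbanocc"
author: "urbanocc maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in urbanocc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`urbanocc` analyses how bird communities and insect pollinators use urban
greenspace sites, combining a hierarchical Bayesian multi-species occupancy
model for robust-design bird surveys with a Poisson log-linear model for
pooled pollinator taxonomic richness. This vignette documents the models,
the sampler, the numerical choices, and the synthetic-data generator that
makes the whole pipeline testable without field data.

## The multi-species occupancy model

Surveys follow a robust design: within each season, visits at each site are
partitioned chronologically into `K = 3` primary sampling periods of `T = 3`
adjacent secondary occasions (with 8 visits the triplets are front-loaded:
3, 3, 2). Occupancy may change between primary periods; closure is assumed
within them. For species $i$, site $j$, primary period $k$ and secondary
occasion $t$:

$$z_{ijk} \mid \psi_{ijk} \sim \mathrm{Bernoulli}(\psi_{ijk}), \qquad
  y_{ijkt} \mid z_{ijk}, p_{ijkt} \sim \mathrm{Bernoulli}(z_{ijk}\,p_{ijkt})$$

with logit-linear predictors

$$\mathrm{logit}(\psi_{ijk}) = \alpha_{0i} + \boldsymbol\alpha_i' X_j, \qquad
  \mathrm{logit}(p_{ijkt}) = \beta_{0ik} + \boldsymbol\beta_i' X_{jkt}.$$

Site covariates (ten, at local/neighborhood/landscape scales) are constant
within a season, so incidence is conditionally independent across primary
periods given the species' occupancy probability — the "stacked"
single-season robust-design formulation. Each season is fitted
independently: a linked multi-season (colonization/extinction) model is
deliberately out of scope because between-season turnover here reflects
migration, not site-driven dynamics, and would force a common species list
across seasons. Only species with at least one detection in a season enter
that season's model; `z` is fixed to 1 wherever the species was detected.

Detection varies over time through a separate intercept $\beta_{0ik}$ per
primary period per species (the default; this also absorbs within-season
migration trends), plus four visit covariates: standardized Julian day, its
square (built from the standardized linear term, so the quadratic is exact
on the model scale), minutes after sunrise, and ambient noise (dB
L~eq~). Missing visits are masked and excluded from the likelihood — no
imputation; a masked visit contributes exactly zero (verified in the test
suite by comparing against data with the visit physically absent).

Species coefficients are exchangeable draws from community distributions,
one family per coefficient: $\alpha_{0i} \sim N(\mu_f, \sigma^2_f)$ and so
on. The hyperpriors are $\mu_f \sim N(0, \sigma^2 = 2.72)$ — on the logit
scale this implies a near-uniform distribution on the probability scale
(tested by simulation: the implied density ratio over (0.05, 0.95) is
below 2) — and $\sigma^2_f \sim \mathrm{InvGamma}(0.1, 0.1)$ with the
shape/rate convention, equivalently precision $\tau_f \sim
\mathrm{Gamma}(0.1, \text{rate } 0.1)$. We place the inverse-gamma on the
community *variance*: that is the conjugate choice, and the prior
simulation test pins the convention down explicitly.

## Sampling

`fit_msom()` runs a Pólya-Gamma augmented Gibbs sampler written for this
package (C++): logistic likelihoods become conditionally Gaussian given
PG(1, η) latent variables, so every update is exact — Bernoulli updates
for `z` at undetected cells, Gaussian updates for species coefficient
blocks, and conjugate Normal/Inverse-Gamma updates for the community
layer. PG(1, z) variables are drawn with Devroye's exact alternating-series
method; the proposal-mixture weight, a smooth univariate function, is
tabulated once on a 1/512 grid and interpolated to near machine precision.
All randomness flows through R's RNG, so a master seed (from which
per-chain seeds are derived) makes fits bit-reproducible. Normal deviates
in the sampler use Box–Muller on that stream.

The defaults mirror the reference protocol: 3 chains, 54,000 iterations,
10,000 burn-in, thinning 10 — 13,200 retained draws. Convergence is
summarized by the Gelman–Rubin statistic for every scalar parameter with
the conventional `R-hat < 1.1` rule; offending parameters are named in a
warning but samples are always returned. Note that the per-period
detection intercepts and the Julian-day terms are intrinsically
correlated (primary periods *are* coarse Julian-day bins), which makes
those blocks the slowest-mixing part of the model; budget burn-in
accordingly on small runs.

The sampler's contract is the posterior, not the kernel: tests compare it
against an independent 2-D grid-quadrature oracle
(`single_species_grid_posterior()`) on single-species models, against an
explicit-loop brute-force log-joint evaluation, and against the truth in
simulation-based coverage studies.

Initialization: `z` starts at the observed maximum over visits,
coefficients at 0, community variances at 1. Site-primary cells with no
conducted visits carry no information; their `z` entries in the returned
incidence array are posterior-predictive draws from each retained draw's
$\psi$, which keeps site-level richness summaries well-defined for
unsurveyed site-seasons.

## Derived quantities

All derived quantities propagate uncertainty draw by draw through the
retained posterior:

- **Richness** sums the latent incidence matrix over any species subset;
  subsets come from urban-tolerance tertiles (below). Incidence at new
  (hypothetical) sites is *sampled*, not thresholded; summing $\psi$
  instead is available separately via `predict_psi()`.
- **Good/poor scenarios** set the six driving covariates (local and
  neighborhood canopy and impervious cover, distances to bay and stream)
  to their observed extremes — maximum or minimum according to the sign of
  their assumed association — and hold every other covariate at its
  standardized mean. All $2^3$ combinations over the three scales are
  enumerated. True observed extremes are used; good and poor are *not*
  assumed to be reflections about the mean.
- **Annual richness** across independently fitted seasons matches draws by
  retained-draw index (chains concatenated in fixed order). Because the
  seasonal posteriors are independent, any index pairing yields the
  correct marginal; a species counts once if present in at least one
  season's draw, and species absent from a season's model contribute
  nothing for that season.
- **p\*** is the cumulative detection probability over visits,
  $1 - \prod_t (1 - p_t)$, computed per draw.
- **Raw-unit effects** ("+10% canopy", "+0.5 km from a stream") are mapped
  to the model scale through the stored standardization record
  (population-scaled: divide-by-$n$ standard deviation), so they are exact
  for the fitted data and invertible to machine tolerance.
- **Species responses** are labeled positive/negative when the 75% HDI
  ("strong") or 95% HDI ("significant") of the slope excludes zero.

## Model checking

- **Posterior predictive check:** per retained draw, replicate detections
  are simulated from that draw's $(z, p)$; the discrepancy
  $T = \sum_g (O_g - E_g)^2 / (E_g + 10^{-6})$ is computed over detection
  counts grouped per species and site, and the Bayesian p-value is the
  proportion of draws with $T^{rep} \ge T^{obs}$ (ties count toward the
  upper side). Values near 0 or 1 signal misfit. The distribution of this
  p-value on data generated from the model is neither uniform nor tightly
  concentrated at 0.5: in our replicate simulations at study scale about
  three quarters of runs fall in (0.2, 0.8), with occasional values near
  0.05 on perfectly well-specified data — so single moderate p-values
  should not be over-read in either direction.
- **HDI:** shortest contiguous interval containing $\lceil m n \rceil$
  sorted draws; for monotone densities it correctly anchors at the
  boundary.
- **Residual spatial autocorrelation:** occupancy residuals
  $r_{ij} = z_{ij} - \psi_{ij}$ (averaged over primary periods within the
  season — the within-season handling is a package choice) are
  mean-centered per draw and summarized as Moran's I in 500 m distance
  bands from 0 to 5 km, per species, with binary weights. Bands with 20 or
  fewer site pairs are flagged and excluded from inference; draws with
  zero residual variance are skipped and counted. An important caveat,
  established during validation: the *fraction of species-band HDIs
  excluding zero* is not a classical test size. On spatially independent
  data fitted with the full model the screen is strongly conservative
  (essentially no exclusions), because posterior uncertainty in $z$ and
  $\psi$ is large relative to the sampling variability of the realized
  residual field; conversely, when detection is nearly perfect the
  posterior of I collapses to an atom at the realized value and exclusions
  become frequent. The diagnostic should be read as a screen for marked
  spatial structure, not as a calibrated 5% test.
- **Pollinator correlogram:** Moran's I per distance class with the class
  count from the Sturges rule, $\lceil 1 + \log_2 n_{pairs} \rceil$, and a
  seeded permutation p-value (999 permutations by default, two-sided
  around the null expectation $-1/(n-1)$).

## Pollinator richness model

Pooled native taxonomic richness per site is modeled as
$y_j \sim \mathrm{Poisson}(\exp(\beta_0 + \boldsymbol\beta' X_j))$ with
the same ten standardized covariates, fitted by maximum likelihood
(`glm`), with Wald 95% intervals ($\hat\beta \pm 1.96\,SE$). There is no
exposure offset by default — richness is pooled over 1–3 visits per site,
matching the survey protocol — but `offset_log_visits = TRUE` provides the
sensitivity variant. Overdispersion is checked with the Pearson statistic
$\phi = \chi^2_P / (n - p)$; the fit is flagged above a configurable
threshold (default 1.5). Pollinator detectability is not modeled: the
survey design had no within-season resurveys, so richness is an index, not
a detection-corrected estimate.

## Urban-tolerance classes

Monthly species-level urban-tolerance scores are averaged over the months
of the seasons in which the species was detected (winter {Nov, Dec, Jan},
spring {Mar, Apr, May}, summer {May, Jun, Jul}, fall {Aug, Sep, Oct}; May
belongs to both spring and summer because the survey windows overlap).
Community tertiles of the averaged scores define the classes: at or below
the 0.33 quantile "urban sensitive", up to the 0.66 quantile "urban
neutral", above it "urban tolerant". Quantiles use linear interpolation
(type 7) and boundary ties go to the lower class; since every species
score is itself an order statistic, the classification is rank-based and
invariant to monotone transformations of the scores. Unscored species are
labeled and excluded from subset richness.

## The synthetic-data generator

`simulate_dataset()` mirrors the generative process the models assume, at
the study's conditions: 45 one-hectare sites in a 6.7 km square (mean
pairwise spacing ≈ 3.5 km), 80 species, four seasons of 3 × 3 robust
design with roughly weekly visits, and 35–44 of 45 sites surveyed per
season (missing completely at random over site-seasons — real gaps were
construction-driven and plausibly non-random, a documented limitation).
Site covariates come from a Gaussian copula with realistic marginals
(scaled Beta for covers and fractions, uniform for distances) and mild
canopy/impervious correlations; all pairwise correlations stay well below
the |0.6| collinearity screen. Community hyperparameters default to mean
occupancy near 0.5 and per-visit detection near 0.15-0.17 (community
average p\* over nine visits around 0.7-0.8), matching the regime the
analysis targets; species
spread is 1.0 (occupancy intercept), 0.5 (occupancy slopes and detection
intercepts) and 0.25 (detection slopes) on the logit scale. Pollinator
counts are Poisson with a log-linear site model whose nonzero defaults
(negative local canopy and impervious effects, negative distance-to-bay
effect) reproduce the qualitative pattern the richness model is meant to
detect. The same master seed yields bit-identical datasets and CSV files.

What the generator does *not* emulate: spatially structured covariates or
residual spatial autocorrelation (sites are exchangeable in space),
non-random missingness, species interactions, unmodeled detection
heterogeneity, and open populations within seasons. Passing tests
demonstrate that the estimators recover the generative process they
assume, not that the assumptions hold for any particular field dataset.

## Validation studies and problem sizes

The test suite runs, at sizes chosen to keep the full suite comfortably
under half an hour on one core:

- sampler vs. exact 2-D quadrature on 1 species × 4 sites × 3 visits;
- log-joint vs. explicit-loop brute force (1e-10) on random 3 × 4
  instances;
- 20 replicate simulate-and-refit studies at 40 species × 45 sites with
  reduced MCMC (3 chains × 6,000 iterations), checking 95% HDI coverage of
  every community mean and posterior-predictive calibration;
- residual-correlogram screening on those fits (spatially independent
  truth);
- 40 replicate Poisson recoveries at n = 500 sites (±2 SE coverage pooled
  over coefficients, dispersion near 1);
- closed-form identities (p\*, subset additivity, HDI vs. normal
  quantiles, annual-richness union vs. brute-force set operations).

`scripts/acceptance.R` re-runs the main pipeline end to end on one
synthetic community and writes the headline numbers as JSON.

## Known limitations

- Occupancy is "use of the site during the season": closure violations
  from migration are mitigated, not eliminated, by period-specific
  detection intercepts.
- The ratio of native to non-native trees is undefined when there are no
  non-native trees; the package uses the proportion native
  (native / total) as the covariate.
- Coordinates must arrive as planar meters; the package never reprojects.
- Seasonal models share summer vegetation measurements in the source
  protocol; nothing in the package corrects for that.
- The Moran's I HDI screen is conservative by construction (see above).
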