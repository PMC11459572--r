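---
title: "Model-based geostatistical mapping of fertility rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based geostatistical mapping of fertility rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertimap)
```

## The problem

Demographic and Health Surveys (DHS) record complete birth histories for
women aged 15–49 in a few thousand georeferenced clusters. From these one
can estimate age-specific fertility rates (ASFR — births per woman-year in
each 5-year age group) and the total fertility rate (TFR = 5 × ΣASFR)
directly, but only where clusters were sampled. Model-based geostatistics
borrows strength across space: cluster-level rates are regressed on gridded
covariates (travel time to a city, distance to a health facility, altitude,
population density, religious composition) with a spatially correlated
random effect, and the fitted model predicts a continuous fertility surface
that can be aggregated to districts, zones, regions and the nation.

`fertimap` implements that pipeline end to end, together with a seeded
synthetic-data generator so every stage can be verified against known truth
at desk scale.

## Direct rate estimation

All date arithmetic uses the DHS century-month code (CMC): dates are whole
months, ages are month differences. The exposure window is the right-closed
interval of 36 months ending at the interview month — the interview month
itself is included, matching the convention that a birth reported "this
month" falls inside "the three years before the survey". Within the window
a woman contributes exposure to the age group her age in months falls in
(boundaries at exact multiples of 60 months, lower-inclusive, across
[180, 600) months); every month of the window is attributed exactly once,
so exposure conservation holds as an integer identity, which the tests
assert against a month-by-month loop.

Births are assigned to the mother's age group at the birth month. Births
delivered below age 15 or at 50 and over are excluded from the numerators
and reported as a weighted diagnostic tally rather than silently dropped.
Weighted totals use the survey design weights; a group with zero exposure
contributes 0 to the TFR and clears a completeness flag instead of
propagating NaN.

## Covariate harmonization

Rasters live on a flat projected kilometre plane (real-data users must
project first; no geodesic arithmetic is attempted). Harmonization to the
~1 km analysis grid resamples by area-weighted means when coarsening and
bilinear interpolation when refining; resampling an already-conforming
raster is bit-identical. Cluster-level covariates are buffer means — 2 km
for urban and 5 km for rural clusters, absorbing the random displacement
applied to published DHS coordinates. Buffer membership is decided by cell
centre, not partial-area intersection: simpler, deterministic, and exact to
test by brute-force enumeration. Columns of the design matrix are
standardized to mean 0, sd 1, and the constants are stored so prediction
rasters get the identical transform; coefficients are therefore per-SD
effects. A collinearity screen flags any pair with |r| ≥ 0.7 (inclusive at
the boundary).

## Bayesian kriging of the religion covariate

The proportion of Muslim women is observed only at clusters and is carried
onto the grid by kriging under a constant-mean Matérn Gaussian process with
nugget. "Bayesian" here means full integration over a discrete
hyperparameter grid rather than MCMC: an 11 × 11 × 5 log-spaced grid over
(partial sill, range, nugget) with smoothness fixed at ν = 1, Gaussian
marginal likelihood at each node, independent log-normal priors centred on
data-driven anchors (the sample variance, a quarter of the bounding-box
diagonal, a tenth of the variance; sdlog 1.5), and prediction as the
weight-mixed conditional mean with mixture variance (within + between).
This is deterministic and exactly testable against a dense brute-force GP
oracle. Proportions are treated on the identity scale and the mixed mean is
clipped to [0, 1]; a logit link would be the natural extension point.
Ordinary (constant-mean) kriging is used; no covariates assist the
interpolation.

Throughout, the Matérn correlation uses the range convention κ =
√(8ν)/φ, so φ is the distance at which correlation falls to ≈ 0.1 (0.13 at
ν = 1), and ν = 0.5 reduces to exp(−2d/φ).

## The geostatistical model

The response is the cluster-level direct TFR (or summed ASFR = TFR/5) and
the model is a Gaussian GAM:

y_i = β₀ + Σ_j β_j X_{j,i} + Σ_k f_k(X_{k,i}) + μ(s_i) + ε_i,

with mean-zero Gaussian priors on β (sd 10 on standardized covariates),
penalized cubic B-spline smooths f_k (second-difference penalty; quantile
knots; partition of unity), a Matérn Gaussian-process random effect μ, and
iid Gaussian noise ε. Because the likelihood is Gaussian, conditioning on
the hyperparameters gives the latent posterior *exactly* in closed form —
the Laplace approximation step of deterministic Bayesian inference is exact
here — so the package fits by exact Gaussian conditioning per node of a
hyperparameter grid (sill, range, nugget; flat prior on the grid) and mixes
over nodes by marginal likelihood. This replaces the triangulated-mesh SPDE
route of large-scale software with an exact dense Gaussian process over the
cluster sites: the same target model, feasible up to a few thousand sites,
and verifiable to 1e-8 against brute-force dense linear algebra. That
replacement is the single structural difference from the large-scale
computational route.

Summaries (posterior mean, sd, 95% credible interval) are
Gaussian-mixture moments across nodes, with quantiles found by bisection on
the mixture CDF to 1e-6. Model comparison uses the grid-average log
marginal likelihood ("evidence"); ties in node weights are kept as weights,
never argmax. All five covariates enter linearly by default — published
coefficient tables print single coefficients per covariate, which is what a
linear term produces; smooths are available via `smoothTerms`.

## Prediction and small-area aggregation

Pixel prediction carries the full joint posterior: fixed-effect
contribution with its covariance, exact GP conditioning of the field at
pixel centres, and the cross-covariance between coefficients and field, so
the pixel variance is the variance of the latent (noise-free) fertility
surface. Node mixing and mixture-CDF quantiles work as in fitting; nodes
are processed in decreasing weight order until 99.9% of posterior mass is
covered. TFR surfaces are floored at 0 (the Gaussian model is unbounded
below).

Aggregation takes the population-weighted mean of pixel means over the
pixels whose centres fall in each admin unit (pixel membership by centre;
snapped borders make this unambiguous), the demographic convention; area
weighting is available behind a flag. Credible bounds are aggregated with
the same weights — an approximation, since exact interval aggregation needs
the joint posterior across pixels; joint simulation is the documented
extension. Zero-population units fall back to unweighted means with a
flag. National = population-weighted mean of regions holds to 1e-9 by
construction, and every unit estimate is a convex combination of its member
pixels.

## The synthetic-data generator

The generator emulates the data-generating structure the analysis assumes:

* **World**: a 100 × 100 km region on a 1 km grid; distance-to-city and
  distance-to-facility layers from seeded point sets (snapped to pixel
  centres, so the distance is exactly 0 at the seeded pixel), altitude and
  log-normal population density from smoothed random surfaces.
* **Latent field**: a Matérn GP (default σ² = 0.5, range 30 km, ν = 1)
  drawn by dense Cholesky on a ≤ 50 × 50 coarse lattice and bilinearly
  refined — exact at lattice nodes, slightly smoothed between, negligible
  when the range is much larger than the lattice spacing.
* **Survey**: 250 clusters (500 × 25 women for the recovery study) placed
  uniformly; the fraction nearest the cities is flagged urban; two-stratum
  design weights (urban 0.8, rural 1.25 before scaling) normalized to mean
  1 — no nonresponse adjustment is modelled.
* **Fertility**: local true TFR(s) = 4.5 + Σ β_j z_j(s) + μ(s), floored at
  0.2 to keep the Gaussian linear predictor from implying negative rates,
  with β of the magnitudes reported for these covariates (0.42 travel
  time, 0.17 facility distance, 0.14 altitude, −0.01 population density,
  0.37 proportion Muslim, per covariate SD). Women get interview ages
  uniform on [15, 50) in whole months; each age-group segment of the
  36-month window generates Poisson births at rate exposure ×
  baseASFR[a] × TFR(s)/TFR_base, with birth months uniform in the segment.
  The Poisson-segment construction keeps the direct estimator unbiased by
  design. The base schedule (0.10, 0.20, 0.21, 0.17, 0.12, 0.07, 0.03
  births/woman-year) sums to 0.90, i.e. base TFR 4.5.
* **Religion**: a smooth logistic surface (logit baseline 0.35 plus a
  Matérn field) supplies the true proportion-Muslim map; observed cluster
  proportions are binomial draws from it, which gives the kriging stage a
  realistic noisy input.
* **Admin units**: nested rectangular partitions (regions → zones →
  districts) with break lines snapped to the grid, near-equal strips with
  a seeded ±1-cell jitter.

One master seed drives everything through named substreams, so each stage
is individually reproducible and the whole pipeline is byte-deterministic
(the tests compare MD5 manifests of two runs).

What the generator does **not** emulate: GPS displacement of cluster
coordinates (the buffer averaging exists to absorb it, but coordinates are
generated undisplaced), non-rectangular geography, multi-survey temporal
structure, age-specific covariate effects, and real-world covariate
distributions. Passing tests demonstrate internal consistency of the
machinery under the assumed model, not performance on real DHS microdata.

## Numerical choices

* Cholesky with escalating diagonal jitter (from 1e-8 of the mean
  diagonal, ×10 steps, hard stop at 1e-2), with the jitter named in the
  error when factorization still fails.
* Mixture quantiles by bisection, tolerance 1e-6.
* The near-flat fixed-effect prior (sd 10) is on standardized covariates;
  using, say, sd 1e3 in tests reproduces least squares to 1e-6.
* Spline penalty λD'D is rank-deficient (linear null space); a 1e-4 ridge
  makes the implied prior proper.
* Node pruning at prediction keeps nodes covering 99.9% of posterior mass
  (99% inside the orchestrated run), renormalized.

## Problem sizes and study conditions

The recovery study uses 500 clusters × 25 women over 50 replicates
(recovery averaged over the first 20 seeds; interval coverage over all
50), with reduced 3 × 3 × 3 kriging and 5 × 5 × 5 model hyper grids per
replicate. Model selection uses 150 clusters × 40 women with field
variance 3 (strong-field scenario, well above the direct-estimator noise
in a cluster) or 0 (no-field scenario). The orchestrated example run uses
250 clusters on the 100 km world with a 2 km prediction grid. These sizes
were chosen as the smallest at which the Monte-Carlo checks are stable.

A note on the intercept: in any single replicate the fitted intercept
absorbs the realized regional mean of the latent field (a zero-mean GP has
a nonzero average over a finite region — its standard deviation here is
about 0.2), so intercept "recovery" is only meaningful as an average over
replicates. The covariate effects do not suffer from this.

## Known limitations

* Gaussian likelihood on cluster-level rates; no Poisson/binomial option.
* Per-survey fitting only — no temporal random effects across survey
  rounds.
* CrI aggregation is the weighted-bound approximation described above.
* Kriging of proportions on the identity scale with clipping.
* Exact GP conditioning scales as O(n³) in clusters; beyond a few thousand
  sites a sparse (SPDE-type) approximation would be needed.
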