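Package: fertimap
Title: Model-Based Geostatistical Mapping of Fertility Rates from Cluster Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates total and age-specific fertility rates (TFR, ASFR) from
    DHS-style birth histories with sampling weights, harmonizes covariate
    rasters to a common kilometre grid, interpolates cluster-level proportions
    by Bayesian kriging, fits Gaussian generalized additive models with and
    without a Matern spatial random effect by exact Gaussian conditioning over
    a hyperparameter grid, and predicts and aggregates fertility surfaces to
    district, zone, region and national levels. Ships a seeded synthetic-data
    generator (two-stage cluster surveys, birth histories driven by a latent
    Matern field, smooth covariate rasters, nested admin units) so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, splines, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'matern.R'
    'grid-methods.R'
    'simulate.R'
    'rates.R'
    'covariates.R'
    'kriging.R'
    'geostat.R'
    'prediction.R'
    'pipeline.R'
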