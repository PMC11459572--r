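# Shared fixture builders: everything is generated in code at test time.

# A small synthetic world for fast end-to-end checks.
tinyConfig <- function(seed = 1, nClusters = 60, womenPerCluster = 20, ...) {
  simulationConfig(extent = c(xmin = 0, xmax = 60, ymin = 0, ymax = 60),
                   nClusters = nClusters, womenPerCluster = womenPerCluster,
                   nCities = 3, nFacilities = 15, seed = seed, ...)
}

# Simulate one replicate of the full survey world and return the pieces the
# downstream stages need. Uses the generator's true religion surface in the
# stack; the analysis harness swaps in the kriged layer where wanted.
simWorld <- function(config) {
  stack <- simulateCovariateRasters(config)
  grid <- gridSpec(stack)
  field <- simulateMaternField(grid, config@matern,
                               fertimap:::substreamSeed(config@seed, "field"))
  religion <- simulateReligionSurface(config)
  genStack <- covariateStack(c(stack@layers, list(prop_muslim = religion)))
  clusters <- simulateClusters(config)
  women <- simulateBirthHistories(clusters, genStack, field, config)
  list(config = config, stack = stack, grid = grid, field = field,
       religion = religion, genStack = genStack, clusters = clusters,
       women = women)
}

# Cluster-level direct TFR aligned with the cluster table order.
clusterTfr <- function(women, clusters) {
  cr <- ratesBy(women, clusters, "cluster")
  vapply(cr[clusters$cluster_id], tfr, numeric(1))
}

# One full estimation replicate: simulate, direct rates, kriged religion
# covariate, buffer design matrix, spatial fit. Reduced hyper grids keep a
# replicate light; sizes are stated in the package vignette.
recoveryReplicate <- function(seed, nClusters = 500, womenPerCluster = 25) {
  cfg <- simulationConfig(seed = seed, nClusters = nClusters,
                          womenPerCluster = womenPerCluster)
  w <- simWorld(cfg)
  y <- clusterTfr(w$women, w$clusters)
  props <- simulateClusterProportions(w$clusters, w$religion, cfg)
  kgrid <- list(sigma2 = var(props$proportion) * c(0.3, 1, 3),
                rangeKm = c(10, 25, 60), nugget = var(props$proportion) *
                  c(1e-6, 0.1, 0.5))
  kf <- krigeFit(props$x_km, props$y_km, props$proportion,
                 nWeights = props$n_women, hyperGrid = kgrid)
  km <- krigePredict(kf, w$grid, weightCutoff = 0.99)$mean
  km@name <- "prop_muslim"
  aStack <- covariateStack(c(w$stack@layers, list(prop_muslim = km)))
  design <- buildDesignMatrix(w$clusters, aStack)
  fit <- suppressWarnings(
    fitGeostat(y, design, cbind(w$clusters$x_km, w$clusters$y_km),
               spatial = TRUE))
  list(fit = fit, truth = c(intercept = cfg@trueIntercept, cfg@trueBeta),
       summary = posteriorSummary(fit))
}

# Independent dense multivariate-normal log density (solve/determinant
# route, no Cholesky), used as the likelihood oracle.
denseMvnLogLik <- function(y, V) {
  n <- length(y)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + sum(y * solve(V, y)))
}

# Model-selection replicate: simulate a survey with a given latent-field
# variance, fit spatial and non-spatial models to cluster TFR, and return
# the evidence difference (spatial minus non-spatial).
modelSelectionReplicate <- function(seed, fieldSigma2, nClusters = 150,
                                    womenPerCluster = 40) {
  cfg <- simulationConfig(seed = seed, nClusters = nClusters,
                          womenPerCluster = womenPerCluster,
                          matern = maternParams(fieldSigma2, 30, 1))
  w <- simWorld(cfg)
  y <- clusterTfr(w$women, w$clusters)
  design <- buildDesignMatrix(w$clusters, w$genStack)
  loc <- cbind(w$clusters$x_km, w$clusters$y_km)
  fs <- suppressWarnings(fitGeostat(y, design, loc, spatial = TRUE))
  fn <- suppressWarnings(fitGeostat(y, design, spatial = FALSE))
  compareModels(fs, fn)
}

# Brute-force month-by-month oracle for exposure: walk every calendar
# month of the window and tally woman-years by age group.
oracleExposure <- function(dob, doi, windowMonths = 36L) {
  months <- numeric(7); out <- 0
  for (m in (doi - windowMonths + 1):doi) {
    age <- m - dob
    if (age >= 180 && age < 600) {
      g <- (age - 180) %/% 60 + 1
      months[g] <- months[g] + 1
    } else out <- out + 1
  }
  list(years = months / 12, outOfRange = out / 12)
}
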