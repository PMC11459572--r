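# Bayesian kriging of a cluster-level proportion onto the prediction grid.
#
# "Bayesian" here means full integration over a discrete hyperparameter
# grid: for each (sigma2, range, nugget) node the Gaussian marginal
# likelihood of the data under a constant-mean Matern GP is combined with
# independent log-normal priors, and predictions are mixed over the
# normalized node weights. Deterministic by construction (no MCMC).

defaultKrigeGrid <- function(z, coords) {
  s2a <- max(var(z), 1e-6)
  diag_km <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
  diag_km <- max(diag_km, 1e-3)
  list(sigma2 = s2a * exp(seq(log(0.05), log(5), length.out = 11)),
       rangeKm = diag_km * exp(seq(log(0.03), log(1), length.out = 11)),
       nugget = s2a * c(1e-8, 0.01, 0.05, 0.2, 1))
}

# Gaussian log marginal likelihood of z under N(mu0, s2 R + tau I), with R
# precomputed from a correlation-matrix cache keyed by range.
gpLogLik <- function(zc, R, s2, tau) {
  C <- s2 * R
  diag(C) <- diag(C) + tau
  L <- cholJitter(C)
  alpha <- backsolve(L, forwardsolve(t(L), zc))
  -0.5 * length(zc) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(alpha^2)
}

#' Fit a Bayesian kriging model to cluster proportions
#'
#' Evaluates the Gaussian marginal likelihood of the observed proportions
#' under a constant-mean Matern Gaussian process plus nugget at every node
#' of a log-spaced (sigma2, range, nugget) grid (smoothness fixed), applies
#' independent log-normal priors centred on data-driven anchors (the sample
#' variance, a quarter of the bounding-box diagonal, a tenth of the sample
#' variance; sdlog 1.5 each), and normalizes the node weights. The prior
#' mean is the \code{nWeights}-weighted mean of the observations.
#'
#' @param x,y data locations (km).
#' @param z observed values in [0, 1] (proportions).
#' @param nWeights optional weights for the prior mean (e.g. numbers of
#'   women per cluster); default equal.
#' @param nu fixed Matern smoothness (default 1).
#' @param hyperGrid optional list(sigma2, rangeKm, nugget) of node values;
#'   default 11 x 11 x 5 grid.
#' @return a \linkS4class{KrigeFit}.
#' @export
krigeFit <- function(x, y, z, nWeights = NULL, nu = 1, hyperGrid = NULL) {
  if (length(z) < 5) stop("need at least 5 points")
  if (any(z < 0 | z > 1)) stop("values must be proportions in [0, 1]")
  coords <- cbind(x, y)
  if (is.null(hyperGrid)) hyperGrid <- defaultKrigeGrid(z, coords)
  if (is.null(nWeights)) nWeights <- rep(1, length(z))
  mu0 <- sum(nWeights * z) / sum(nWeights)
  zc <- z - mu0
  s2a <- max(var(z), 1e-6)
  diag_km <- max(sqrt(sum((apply(coords, 2, max) -
                           apply(coords, 2, min))^2)), 1e-3)
  nodes <- expand.grid(sigma2 = hyperGrid$sigma2,
                       rangeKm = hyperGrid$rangeKm,
                       nugget = hyperGrid$nugget)
  Rcache <- lapply(hyperGrid$rangeKm, function(phi)
    maternCorrMatrix(coords, phi, nu))
  names(Rcache) <- as.character(hyperGrid$rangeKm)
  nodes$logLik <- vapply(seq_len(nrow(nodes)), function(i)
    gpLogLik(zc, Rcache[[as.character(nodes$rangeKm[i])]],
             nodes$sigma2[i], nodes$nugget[i]), numeric(1))
  nodes$logPrior <- dlnorm(nodes$sigma2, log(s2a), 1.5, log = TRUE) +
    dlnorm(nodes$rangeKm, log(diag_km / 4), 1.5, log = TRUE) +
    dlnorm(pmax(nodes$nugget, 1e-12), log(0.1 * s2a), 1.5, log = TRUE)
  lw <- nodes$logLik + nodes$logPrior
  nodes$weight <- exp(lw - logSumExp(lw))
  new("KrigeFit", x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
      mu0 = mu0, nu = nu, nodes = nodes)
}

setMethod("show", "KrigeFit", function(object) {
  top <- object@nodes[order(-object@nodes$weight), ][1:3, ]
  cat(sprintf("KrigeFit: %d points, prior mean %.4f, %d hyper nodes\n",
              length(object@z), object@mu0, nrow(object@nodes)))
  cat("top nodes (sigma2, range km, nugget, weight):\n")
  for (i in 1:3)
    cat(sprintf("  %.4g  %.4g  %.4g  %.3f\n", top$sigma2[i], top$rangeKm[i],
                top$nugget[i], top$weight[i]))
})

#' @describeIn posteriorSummary hyperparameter posterior of a kriging fit:
#'   weighted means of sigma2, range and nugget.
#' @export
setMethod("posteriorSummary", "KrigeFit", function(x, ...) {
  w <- x@nodes$weight
  c(sigma2 = sum(w * x@nodes$sigma2), rangeKm = sum(w * x@nodes$rangeKm),
    nugget = sum(w * x@nodes$nugget))
})

#' Posterior summaries
#' @param x a fitted object.
#' @param ... method-specific arguments.
#' @name posteriorSummary
NULL

#' Kriging prediction surfaces
#'
#' Per hyper node the exact Gaussian-process conditional mean and variance
#' of the noise-free surface at every pixel centre, then mixed over node
#' weights (mixture mean; mixture variance = within-node + between-node).
#' The mean is clipped to [0, 1] after mixing. Nodes are processed in
#' decreasing weight order until \code{weightCutoff} of the posterior mass
#' is covered.
#'
#' @param fit a \linkS4class{KrigeFit}.
#' @param grid target \linkS4class{GridSpec}.
#' @param weightCutoff cumulative node-weight coverage (default 0.9999).
#' @return list of two \linkS4class{RasterLayer}s: \code{mean} and \code{sd}.
#' @export
krigePredict <- function(fit, grid, weightCutoff = 0.9999) {
  coords <- cbind(fit@x, fit@y)
  pc <- pixelCenters(grid)
  # sanity warning when the grid is far outside the data footprint
  rng <- sum(fit@nodes$weight * fit@nodes$rangeKm)
  lo <- apply(coords, 2, min) - 3 * rng; hi <- apply(coords, 2, max) + 3 * rng
  ge <- extentOf(grid)
  if (ge["xmax"] < lo[1] || ge["xmin"] > hi[1] ||
      ge["ymax"] < lo[2] || ge["ymin"] > hi[2])
    warning("prediction grid lies far outside the data footprint")
  ord <- order(-fit@nodes$weight)
  keep <- ord[seq_len(which(cumsum(fit@nodes$weight[ord]) >=
                            weightCutoff)[1])]
  w <- fit@nodes$weight[keep]; w <- w / sum(w)
  zc <- fit@z - fit@mu0
  npix <- nrow(pc)
  m1 <- numeric(npix); m2 <- numeric(npix)
  Dcross <- sqrt(outer(pc[, "x"], coords[, 1], "-")^2 +
                 outer(pc[, "y"], coords[, 2], "-")^2)
  for (j in seq_along(keep)) {
    nd <- fit@nodes[keep[j], ]
    R <- maternCorrMatrix(coords, nd$rangeKm, fit@nu)
    C <- nd$sigma2 * R
    diag(C) <- diag(C) + nd$nugget
    L <- cholJitter(C)
    K <- nd$sigma2 * maternCorrelation(as.vector(Dcross), nd$rangeKm, fit@nu)
    K <- matrix(K, npix, length(zc))
    alpha <- backsolve(L, forwardsolve(t(L), zc))
    mu <- fit@mu0 + as.vector(K %*% alpha)
    V <- forwardsolve(t(L), t(K))
    v <- pmax(nd$sigma2 - colSums(V^2), 0)
    m1 <- m1 + w[j] * mu
    m2 <- m2 + w[j] * (v + mu^2)
  }
  sdv <- sqrt(pmax(m2 - m1^2, 0))
  m1 <- pmin(pmax(m1, 0), 1)
  list(mean = rasterLayer(matrix(m1, grid@nRows, grid@nCols), grid,
                          "krige_mean"),
       sd = rasterLayer(matrix(sdv, grid@nRows, grid@nCols), grid,
                        "krige_sd"))
}
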