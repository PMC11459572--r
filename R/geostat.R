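# Gaussian GAM with optional Matern spatial random effect, fitted by exact
# Gaussian conditioning per hyperparameter node and grid integration over
# the nodes (the Gaussian likelihood makes the Laplace step exact, so this
# reproduces deterministic-Bayes inference without a triangulated mesh:
# the latent field is handled as an exact GP over the cluster sites).
#
# Model: y_i = b0 + sum_j b_j X_ji + sum_k f_k(X_ki) + u(s_i) + e_i with
# b ~ N(0, priorSdBeta^2), f_k penalized cubic B-splines, u a Matern GP
# (sigma2, range, nu) and e_i iid N(0, nugget).

#' Cubic B-spline basis with a second-difference penalty
#'
#' Full cubic B-spline basis on quantile-spaced interior knots over the
#' observed range (rows sum to 1: partition of unity), and the
#' second-difference penalty matrix on the coefficients (zero on linear
#' coefficient sequences).
#'
#' @param x numeric covariate values.
#' @param K basis size (>= 4).
#' @return list: \code{B} (n x K basis), \code{P} (K x K penalty),
#'   \code{knots} (the full knot vector, reusable for prediction).
#' @export
splineBasis <- function(x, K) {
  if (K < 4) stop("K must be >= 4")
  if (!all(is.finite(x))) stop("x must be finite")
  if (length(unique(x)) < K)
    stop("fewer distinct x values than basis functions")
  lo <- min(x); hi <- max(x)
  nInterior <- K - 4
  interior <- if (nInterior > 0)
    quantile(x, probs = seq_len(nInterior) / (nInterior + 1), names = FALSE)
  else numeric()
  knots <- c(rep(lo, 4), interior, rep(hi, 4))
  B <- splines::splineDesign(knots, x, ord = 4)
  D <- diff(diag(K), differences = 2)
  list(B = B, P = crossprod(D), knots = knots)
}

evalSplineBasis <- function(knots, x) {
  lo <- knots[1]; hi <- knots[length(knots)]
  splines::splineDesign(knots, pmin(pmax(x, lo), hi), ord = 4)
}

# Assemble Z (all coefficient columns) and the prior covariance blocks.
# smooth: list(terms = chr, K = int, bases = list per term). Returns
# list(Z, Bdiag = prior covariance matrix of coefficients) for one lambda.
assembleCoefModel <- function(X, priorSdBeta, smooth, lambda) {
  p <- ncol(X)
  Z <- X
  Bblocks <- list(diag(priorSdBeta^2, p))
  if (length(smooth$terms)) {
    for (k in seq_along(smooth$terms)) {
      bs <- smooth$bases[[k]]
      Z <- cbind(Z, bs$B)
      Pl <- lambda[k] * bs$P + diag(1e-4, ncol(bs$B))
      Bblocks[[length(Bblocks) + 1L]] <- solve(Pl)
    }
  }
  q <- sum(vapply(Bblocks, nrow, integer(1)))
  B <- matrix(0, q, q)
  at <- 0
  for (blk in Bblocks) {
    ix <- at + seq_len(nrow(blk)); B[ix, ix] <- blk; at <- at + nrow(blk)
  }
  list(Z = Z, B = B)
}

#' Marginal log-likelihood of the Gaussian GAM at one hyper node
#'
#' Log density of the responses under the marginal Gaussian obtained by
#' integrating out all coefficients and the spatial field analytically:
#' covariance \code{priorSdBeta^2 Z Z' (+ smooth blocks) + sigma2 *
#' MaternCorr(locations) + nugget * I}, evaluated by Cholesky
#' factorization.
#'
#' @param y response vector.
#' @param X design matrix of fixed-effect columns (include the intercept
#'   column yourself, or pass NULL for a pure field model).
#' @param locations n x 2 coordinate matrix (km); NULL when
#'   \code{sigma2 = 0}.
#' @param sigma2,rangeKm,nugget,nu Matern / noise hyper values.
#' @param priorSdBeta sd of the mean-zero Gaussian prior on columns of X.
#' @return the log marginal likelihood (scalar).
#' @export
marginalLoglik <- function(y, X = NULL, locations = NULL, sigma2 = 0,
                           rangeKm = 1, nugget = 1, nu = 1,
                           priorSdBeta = 10) {
  n <- length(y)
  V <- diag(nugget, n)
  if (sigma2 > 0) {
    if (is.null(locations)) stop("locations required when sigma2 > 0")
    V <- V + sigma2 * maternCorrMatrix(locations, rangeKm, nu)
  }
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (n < ncol(X)) stop("need at least as many observations as columns")
    V <- V + priorSdBeta^2 * tcrossprod(X)
  }
  L <- cholJitter(V)
  alpha <- forwardsolve(t(L), y)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(alpha^2)
}

defaultGeostatGrid <- function(y, locations, spatial) {
  vy <- max(var(y), 1e-6)
  if (!spatial)
    return(list(sigma2 = 0, rangeKm = 1,
                nugget = vy * exp(seq(log(0.05), log(2), length.out = 15))))
  diag_km <- max(sqrt(sum((apply(locations, 2, max) -
                           apply(locations, 2, min))^2)), 1e-3)
  list(sigma2 = vy * exp(seq(log(0.05), log(2), length.out = 5)),
       rangeKm = diag_km * exp(seq(log(0.05), log(0.8), length.out = 5)),
       nugget = vy * exp(seq(log(0.05), log(1), length.out = 5)))
}

# Per-node exact Gaussian posterior of the coefficients (and implicitly the
# field). Returns postMean, postCov for theta = (fixed, spline coefs),
# plus the Cholesky pieces predictPixels needs.
nodePosterior <- function(y, Z, B, C) {
  V <- Z %*% B %*% t(Z) + C
  L <- cholJitter(V)
  Vinv_y <- backsolve(L, forwardsolve(t(L), y))
  Vinv_Z <- backsolve(L, forwardsolve(t(L), Z))
  BZt <- B %*% t(Z)
  postMean <- as.vector(BZt %*% Vinv_y)
  postCov <- B - BZt %*% Vinv_Z %*% B
  logML <- -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) -
    0.5 * sum(y * Vinv_y)
  list(postMean = postMean, postCov = postCov, logML = logML, L = L,
       Vinv_y = Vinv_y, Vinv_Z = Vinv_Z)
}

#' Fit the geostatistical Gaussian GAM
#'
#' For every node of the hyperparameter grid (Matern sigma2 and range plus
#' the nugget; penalty values when smooth terms are present) the posterior
#' of the intercept, fixed effects, spline coefficients and field values is
#' exactly Gaussian and is computed in closed form; node weights are
#' proportional to the marginal likelihood under a flat prior on the grid.
#' Fixed-effect summaries (posterior mean, sd, 95% credible interval) are
#' weighted Gaussian-mixture moments with quantiles found by bisection on
#' the mixture CDF. The mixed log marginal likelihood (grid-average
#' evidence) supports comparison of models with and without the spatial
#' term.
#'
#' @param y response vector (cluster-level TFR or summed ASFR).
#' @param design \linkS4class{DesignMatrix} or plain matrix of standardized
#'   covariates (no intercept column; one is added).
#' @param locations n x 2 cluster coordinates (km); required when
#'   \code{spatial}.
#' @param spatial include the Matern spatial random effect?
#' @param priorSdBeta sd of the mean-zero Gaussian prior on the intercept
#'   and fixed effects (default 10, weak on standardized covariates).
#' @param nu fixed Matern smoothness (default 1).
#' @param hyperGrid optional list(sigma2, rangeKm, nugget).
#' @param smoothTerms optional character vector of design columns to model
#'   as penalized smooths instead of linear terms.
#' @param smoothK basis size per smooth term (default 8).
#' @param penaltyGrid penalty values explored per smooth term (log-spaced
#'   default).
#' @param checkCollinearity warn when any |r| >= 0.7 pair is present.
#' @return a \linkS4class{GeostatFit}.
#' @export
fitGeostat <- function(y, design, locations = NULL, spatial = TRUE,
                       priorSdBeta = 10, nu = 1, hyperGrid = NULL,
                       smoothTerms = character(), smoothK = 8,
                       penaltyGrid = 10^seq(-2, 2, length.out = 5),
                       checkCollinearity = TRUE) {
  X <- if (is(design, "DesignMatrix")) design@X else as.matrix(design)
  n <- length(y)
  if (nrow(X) != n) stop("design and response sizes differ")
  if (spatial) {
    if (is.null(locations)) stop("locations required for the spatial model")
    if (n < 10) stop("spatial model needs at least 10 clusters")
    locations <- as.matrix(locations)
  }
  if (checkCollinearity && ncol(X) >= 2) {
    cc <- collinearityCheck(X)
    if (nrow(cc$flagged))
      warning(sprintf("collinear covariate pair(s): %s",
                      paste(cc$flagged$var1, cc$flagged$var2,
                            sep = "~", collapse = ", ")))
  }
  linear <- setdiff(colnames(X), smoothTerms)
  if (!all(smoothTerms %in% colnames(X)))
    stop("smoothTerms must name design columns")
  smooth <- list(terms = smoothTerms, K = smoothK, bases = list())
  for (tm in smoothTerms)
    smooth$bases[[tm]] <- splineBasis(X[, tm], smoothK)
  Xfix <- cbind(intercept = 1, X[, linear, drop = FALSE])
  if (is.null(hyperGrid)) hyperGrid <- defaultGeostatGrid(y, locations, spatial)
  grid <- expand.grid(sigma2 = hyperGrid$sigma2, rangeKm = hyperGrid$rangeKm,
                      nugget = hyperGrid$nugget)
  if (length(smoothTerms)) {
    lam <- do.call(expand.grid, rep(list(penaltyGrid), length(smoothTerms)))
    names(lam) <- paste0("lambda_", smoothTerms)
    grid <- merge(grid, lam, by = NULL)
  }
  Rcache <- new.env()
  corrFor <- function(phi) {
    key <- sprintf("r%.12g", phi)
    if (!exists(key, envir = Rcache, inherits = FALSE))
      assign(key, maternCorrMatrix(locations, phi, nu), envir = Rcache)
    get(key, envir = Rcache, inherits = FALSE)
  }
  pFix <- ncol(Xfix)
  nodeStats <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    nd <- grid[i, ]
    lambda <- if (length(smoothTerms))
      as.numeric(nd[paste0("lambda_", smoothTerms)]) else numeric()
    cm <- assembleCoefModel(Xfix, priorSdBeta, smooth, lambda)
    C <- diag(nd$nugget, n)
    if (spatial && nd$sigma2 > 0)
      C <- C + nd$sigma2 * corrFor(nd$rangeKm)
    np <- nodePosterior(y, cm$Z, cm$B, C)
    nodeStats[[i]] <- list(logML = np$logML,
                           mean = np$postMean[seq_len(pFix)],
                           sd = sqrt(pmax(diag(np$postCov)[seq_len(pFix)], 0)))
  }
  logML <- vapply(nodeStats, `[[`, numeric(1), "logML")
  w <- exp(logML - logSumExp(logML))
  grid$logML <- logML
  grid$weight <- w
  means <- t(vapply(nodeStats, `[[`, numeric(pFix), "mean"))
  sds <- t(vapply(nodeStats, `[[`, numeric(pFix), "sd"))
  mixMean <- as.vector(w %*% means)
  mixVar <- as.vector(w %*% (sds^2 + means^2)) - mixMean^2
  lower <- vapply(seq_len(pFix), function(j)
    mixtureQuantile(0.025, means[, j], sds[, j], w), numeric(1))
  upper <- vapply(seq_len(pFix), function(j)
    mixtureQuantile(0.975, means[, j], sds[, j], w), numeric(1))
  summaryTable <- data.frame(
    term = colnames(Xfix), mean = mixMean, sd = sqrt(pmax(mixVar, 0)),
    lower95 = lower, upper95 = upper, stringsAsFactors = FALSE)
  mixedML <- logSumExp(logML) - log(length(logML))
  new("GeostatFit", y = as.numeric(y), X = Xfix,
      locations = if (spatial) locations else matrix(numeric(), 0, 2),
      spatial = spatial, priorSdBeta = priorSdBeta, nu = nu,
      smooth = smooth, nodes = grid, summaryTable = summaryTable,
      logML = mixedML)
}

setMethod("show", "GeostatFit", function(object) {
  cat(sprintf("GeostatFit (%s), n = %d, log evidence = %.2f\n",
              if (object@spatial) "Matern spatial effect" else "non-spatial",
              length(object@y), object@logML))
  st <- object@summaryTable
  st[, -1] <- round(st[, -1], 3)
  print(st, row.names = FALSE)
})

#' @describeIn posteriorSummary fixed-effect summary table of a
#'   geostatistical fit (term, mean, sd, lower95, upper95).
#' @export
setMethod("posteriorSummary", "GeostatFit", function(x, ...) x@summaryTable)

#' Compare spatial and non-spatial fits
#'
#' Difference in mixed log marginal likelihood (grid-average evidence)
#' between two fits of the same response; the higher-evidence model is
#' flagged as preferred.
#'
#' @param fitSpatial,fitNonspatial \linkS4class{GeostatFit} objects on the
#'   same data.
#' @return list: \code{delta} (spatial minus non-spatial), \code{preferred}
#'   ("spatial" | "nonspatial" | "tie").
#' @export
compareModels <- function(fitSpatial, fitNonspatial) {
  if (length(fitSpatial@y) != length(fitNonspatial@y))
    stop("fits are on different numbers of observations")
  delta <- fitSpatial@logML - fitNonspatial@logML
  preferred <- if (abs(delta) < 1e-9) "tie"
  else if (delta > 0) "spatial" else "nonspatial"
  list(delta = delta, preferred = preferred,
       logML = c(spatial = fitSpatial@logML,
                 nonspatial = fitNonspatial@logML))
}
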