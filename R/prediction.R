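# Pixel-level posterior prediction and small-area aggregation.

#' Posterior fertility surface at pixel level
#'
#' For every retained hyper node the pixel-level posterior is exact: the
#' fixed-effect (and smooth) contribution uses the joint coefficient
#' posterior, the Matern field is conditioned at pixel centres by exact
#' Gaussian-process kriging given the data, and the full covariance between
#' coefficients and field is carried so the pixel variance is the variance
#' of the latent (noise-free) fertility surface. Node results are mixed
#' over posterior weights; the 95% credible bounds come from bisection on
#' the mixture CDF. TFR surfaces are floored at 0 after mixing.
#'
#' @param fit a \linkS4class{GeostatFit}.
#' @param stack \linkS4class{CovariateStack} holding every fitted covariate
#'   on the prediction grid.
#' @param standardization the \linkS4class{DesignMatrix} from training
#'   (its center/scale are replayed on the rasters).
#' @param weightCutoff cumulative node-weight coverage (default 0.999).
#' @param clipAtZero floor the mean and bounds at 0 (fertility rates).
#' @return a \linkS4class{PredictionSurface} on the stack grid.
#' @export
predictPixels <- function(fit, stack, standardization, weightCutoff = 0.999,
                          clipAtZero = TRUE) {
  grid <- gridSpec(stack)
  covNames <- c(setdiff(colnames(fit@X), "intercept"), fit@smooth$terms)
  Xpix <- sapply(covNames, function(nm) {
    v <- as.vector(rasterValues(getLayer(stack, nm)))
    (v - standardization@center[[nm]]) / standardization@scale[[nm]]
  })
  Xpix <- matrix(Xpix, ncol = length(covNames),
                 dimnames = list(NULL, covNames))
  if (any(!is.finite(Xpix)))
    stop("covariate rasters contain nodata inside the prediction grid")
  linear <- setdiff(colnames(fit@X), "intercept")
  Zp <- cbind(intercept = 1, Xpix[, linear, drop = FALSE])
  for (tm in fit@smooth$terms)
    Zp <- cbind(Zp, evalSplineBasis(fit@smooth$bases[[tm]]$knots, Xpix[, tm]))
  npix <- nrow(Zp)
  n <- length(fit@y)
  ord <- order(-fit@nodes$weight)
  keep <- ord[seq_len(which(cumsum(fit@nodes$weight[ord]) >=
                            weightCutoff)[1])]
  w <- fit@nodes$weight[keep]; w <- w / sum(w)
  pc <- pixelCenters(grid)
  meanMat <- matrix(0, npix, length(keep))
  sdMat <- matrix(0, npix, length(keep))
  for (j in seq_along(keep)) {
    nd <- fit@nodes[keep[j], ]
    lambda <- if (length(fit@smooth$terms))
      as.numeric(nd[paste0("lambda_", fit@smooth$terms)]) else numeric()
    cm <- assembleCoefModel(fit@X, fit@priorSdBeta, fit@smooth, lambda)
    C <- diag(nd$nugget, n)
    spatialNode <- fit@spatial && nd$sigma2 > 0
    if (spatialNode)
      C <- C + nd$sigma2 * maternCorrMatrix(fit@locations, nd$rangeKm, fit@nu)
    np <- nodePosterior(fit@y, cm$Z, cm$B, C)
    thetaMean <- np$postMean
    thetaCov <- np$postCov
    mu <- as.vector(Zp %*% thetaMean)
    vv <- rowSums((Zp %*% thetaCov) * Zp)
    if (spatialNode) {
      Dx <- outer(pc[, "x"], fit@locations[, 1], "-")
      Dy <- outer(pc[, "y"], fit@locations[, 2], "-")
      Kp <- nd$sigma2 * maternCorrelation(sqrt(as.vector(Dx^2 + Dy^2)),
                                          nd$rangeKm, fit@nu)
      Kp <- matrix(Kp, npix, n)
      mu <- mu + as.vector(Kp %*% np$Vinv_y)
      H <- forwardsolve(t(np$L), t(Kp))            # n x npix
      vu <- pmax(nd$sigma2 - colSums(H^2), 0)
      # cross term: Cov(theta, u_p | y) = -B Z' V^{-1} k_p
      BZt <- cm$B %*% t(cm$Z)
      Cross <- -BZt %*% backsolve(np$L, H)         # q x npix
      vv <- vv + vu + 2 * colSums(t(Zp) * Cross)
    }
    meanMat[, j] <- mu
    sdMat[, j] <- sqrt(pmax(vv, 0))
  }
  m1 <- as.vector(meanMat %*% w)
  m2 <- as.vector((sdMat^2 + meanMat^2) %*% w)
  sdv <- sqrt(pmax(m2 - m1^2, 0))
  lower <- mixtureQuantile(0.025, meanMat, sdMat, w)
  upper <- mixtureQuantile(0.975, meanMat, sdMat, w)
  if (clipAtZero) {
    m1 <- pmax(m1, 0); lower <- pmax(lower, 0); upper <- pmax(upper, 0)
  }
  lower <- pmin(lower, m1); upper <- pmax(upper, m1)
  toM <- function(v) matrix(v, grid@nRows, grid@nCols)
  new("PredictionSurface", grid = grid, mean = toM(m1), sd = toM(sdv),
      lower95 = toM(lower), upper95 = toM(upper))
}

setMethod("show", "PredictionSurface", function(object) {
  cat(sprintf("PredictionSurface %d x %d: mean [%.3f, %.3f], sd [%.3f, %.3f]\n",
              object@grid@nRows, object@grid@nCols,
              min(object@mean), max(object@mean),
              min(object@sd), max(object@sd)))
})

# Pixel membership (by centre) per admin unit; borders are snapped to grid
# lines so a centre is never ambiguous.
unitPixelIndex <- function(unit, grid) {
  pc <- pixelCenters(grid)
  which(pc[, "x"] >= unit$xmin & pc[, "x"] < unit$xmax &
        pc[, "y"] >= unit$ymin & pc[, "y"] < unit$ymax)
}

#' Aggregate a prediction surface to administrative units
#'
#' Population-weighted mean of the pixel posterior means over the pixels
#' whose centres fall in each unit, at district, zone, region and national
#' level; the credible bounds are aggregated with the same weights (an
#' approximation to the aggregate posterior, which would need the joint
#' pixel distribution). A zero-population unit falls back to the unweighted
#' pixel mean and is flagged.
#'
#' @param surface a \linkS4class{PredictionSurface}.
#' @param admin an \linkS4class{AdminUnits} object (units snapped to the
#'   surface grid).
#' @param pop population \linkS4class{RasterLayer} on the same grid
#'   (nonnegative).
#' @param weighting "population" (default) or "area" (equal pixel weights).
#' @return data.frame: level, unit_id, parent_id, estimate, lower, upper,
#'   population, flag_zero_pop.
#' @export
aggregateSurface <- function(surface, admin, pop,
                             weighting = c("population", "area")) {
  weighting <- match.arg(weighting)
  grid <- surface@grid
  if (!sameGrid(gridSpec(pop), grid))
    stop("population raster is not on the surface grid")
  pv <- as.vector(rasterValues(pop))
  if (any(pv < 0, na.rm = TRUE)) stop("population must be nonnegative")
  pv[is.na(pv)] <- 0
  ge <- extentOf(grid)
  units <- admin@units
  if (any(units$xmin < ge["xmin"] - 1e-9 | units$xmax > ge["xmax"] + 1e-9 |
          units$ymin < ge["ymin"] - 1e-9 | units$ymax > ge["ymax"] + 1e-9))
    stop("admin unit extends outside the prediction grid")
  mv <- as.vector(surface@mean); lv <- as.vector(surface@lower95)
  uv <- as.vector(surface@upper95)
  national <- data.frame(id = "national", level = "national",
                         parent_id = NA_character_, xmin = ge["xmin"],
                         xmax = ge["xmax"], ymin = ge["ymin"],
                         ymax = ge["ymax"], stringsAsFactors = FALSE)
  allUnits <- rbind(national, units)
  rows <- lapply(seq_len(nrow(allUnits)), function(i) {
    u <- allUnits[i, ]
    ix <- unitPixelIndex(u, grid)
    if (!length(ix)) stop(sprintf("unit %s contains no pixel centres", u$id))
    wts <- if (weighting == "population") pv[ix] else rep(1, length(ix))
    zero <- sum(wts) == 0
    if (zero) wts <- rep(1, length(ix))
    wts <- wts / sum(wts)
    data.frame(level = u$level, unit_id = u$id, parent_id = u$parent_id,
               estimate = sum(wts * mv[ix]), lower = sum(wts * lv[ix]),
               upper = sum(wts * uv[ix]), population = sum(pv[ix]),
               flag_zero_pop = zero, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Min-max summary of estimates per administrative level
#'
#' The range of unit estimates at each level with the extremal unit IDs,
#' mirroring the way mapped fertility results are reported (e.g. zone-level
#' TFR ranging between its lowest and highest zones).
#'
#' @param aggregated data.frame from \code{\link{aggregateSurface}}.
#' @return data.frame: level, min, min_unit, max, max_unit.
#' @export
rangeReport <- function(aggregated) {
  levels <- unique(aggregated$level)
  do.call(rbind, lapply(levels, function(lv) {
    d <- aggregated[aggregated$level == lv, ]
    data.frame(level = lv,
               min = min(d$estimate), min_unit = d$unit_id[which.min(d$estimate)],
               max = max(d$estimate), max_unit = d$unit_id[which.max(d$estimate)],
               stringsAsFactors = FALSE)
  }))
}
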