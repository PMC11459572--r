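# Cluster-level covariate extraction and design-matrix construction.

#' Stratified buffer mean of a raster at a point
#'
#' Mean of the cells whose centres lie within the buffer radius of the
#' point: 2 km for urban locations, 5 km for rural ones (absorbing the
#' GPS displacement of survey cluster coordinates). When no cell centre
#' falls inside the buffer the nearest cell's value is returned with a
#' warning.
#'
#' @param layer a \linkS4class{RasterLayer}.
#' @param x,y point coordinates (km); must lie inside the raster extent.
#' @param urban logical; selects the 2 km (urban) or 5 km (rural) radius.
#' @param radiusUrban,radiusRural buffer radii in km.
#' @return the buffer mean (scalar).
#' @export
bufferExtract <- function(layer, x, y, urban, radiusUrban = 2,
                          radiusRural = 5) {
  g <- layer@grid
  e <- extentOf(g)
  if (x < e["xmin"] || x > e["xmax"] || y < e["ymin"] || y > e["ymax"])
    stop(sprintf("point (%.3f, %.3f) lies outside the raster extent", x, y))
  r <- if (isTRUE(urban) || identical(urban, 1L) || identical(urban, 1))
    radiusUrban else radiusRural
  # candidate rows/cols within the bounding square of the buffer
  c0 <- max(1L, as.integer(floor((x - r - g@xOrigin) / g@cellKm)) + 1L)
  c1 <- min(g@nCols, as.integer(ceiling((x + r - g@xOrigin) / g@cellKm)))
  r0 <- max(1L, as.integer(floor((g@yOrigin - (y + r)) / g@cellKm)) + 1L)
  r1 <- min(g@nRows, as.integer(ceiling((g@yOrigin - (y - r)) / g@cellKm)))
  if (c1 >= c0 && r1 >= r0) {
    xc <- g@xOrigin + ((c0:c1) - 0.5) * g@cellKm
    yc <- g@yOrigin - ((r0:r1) - 0.5) * g@cellKm
    d2 <- outer((yc - y)^2, (xc - x)^2, "+")
    vals <- layer@values[r0:r1, c0:c1, drop = FALSE]
    inside <- d2 <= r^2 & !is.na(vals)
    if (any(inside)) return(mean(vals[inside]))
  }
  warning("no cell centre within the buffer; using the nearest cell")
  pc <- pixelCenters(g)
  ok <- which(!is.na(as.vector(layer@values)))
  d2 <- (pc[ok, "x"] - x)^2 + (pc[ok, "y"] - y)^2
  as.vector(layer@values)[ok[which.min(d2)]]
}

#' Build the standardized cluster design matrix
#'
#' One row per cluster and one column per stack layer, filled with
#' stratified buffer means (\code{\link{bufferExtract}}), then each column
#' centred and scaled to unit variance. The standardization constants are
#' kept in the returned object so prediction rasters can be transformed
#' identically.
#'
#' @param clusters cluster data.frame (x_km, y_km, urban).
#' @param stack a \linkS4class{CovariateStack}.
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(clusters, stack) {
  nms <- layerNames(stack)
  X <- sapply(nms, function(nm) {
    ly <- getLayer(stack, nm)
    vapply(seq_len(nrow(clusters)), function(i)
      bufferExtract(ly, clusters$x_km[i], clusters$y_km[i],
                    clusters$urban[i] == 1), numeric(1))
  })
  X <- matrix(X, nrow = nrow(clusters), dimnames = list(NULL, nms))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero <- which(scl == 0 | !is.finite(scl))
  if (length(zero))
    stop(sprintf("zero-variance covariate column: %s",
                 paste(nms[zero], collapse = ", ")))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  new("DesignMatrix", X = Xs, center = ctr, scale = scl)
}

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d clusters x %d standardized covariates (%s)\n",
              nrow(object@X), ncol(object@X),
              paste(colnames(object@X), collapse = ", ")))
})

#' Undo the standardization of a design matrix
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @return the raw (de-standardized) matrix.
#' @export
destandardize <- function(design) {
  sweep(sweep(design@X, 2, design@scale, "*"), 2, design@center, "+")
}

#' Collinearity screen for the design matrix
#'
#' Pearson correlation matrix of the columns; any pair at or above the 0.7
#' threshold in absolute value is flagged (the conventional pass rule being
#' that all pairwise correlations stay below 0.7).
#'
#' @param X a numeric matrix or \linkS4class{DesignMatrix} with >= 2 columns.
#' @param threshold flagging threshold on |r| (inclusive), default 0.7.
#' @return list: \code{correlation} (matrix) and \code{flagged}
#'   (data.frame of offending pairs: var1, var2, r).
#' @export
collinearityCheck <- function(X, threshold = 0.7) {
  if (is(X, "DesignMatrix")) X <- X@X
  if (ncol(X) < 2) stop("need at least two columns")
  if (any(apply(X, 2, sd) == 0)) stop("constant column in the design matrix")
  R <- cor(X)
  ut <- which(upper.tri(R) & abs(R) >= threshold - 1e-9, arr.ind = TRUE)
  flagged <- data.frame(
    var1 = colnames(R)[ut[, 1]], var2 = colnames(R)[ut[, 2]],
    r = R[ut], stringsAsFactors = FALSE)
  list(correlation = R, flagged = flagged)
}
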