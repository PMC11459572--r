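#' Create a grid specification
#'
#' @param xOrigin,yOrigin north-west corner (km): west edge, north edge.
#' @param cellKm cell size (km).
#' @param nRows,nCols dimensions.
#' @return a \linkS4class{GridSpec}.
#' @export
makeGrid <- function(xOrigin, yOrigin, cellKm, nRows, nCols) {
  new("GridSpec", xOrigin = as.numeric(xOrigin), yOrigin = as.numeric(yOrigin),
      cellKm = as.numeric(cellKm), nRows = as.integer(nRows),
      nCols = as.integer(nCols))
}

#' Grid covering a rectangular extent
#'
#' @param extent named numeric (xmin, xmax, ymin, ymax), km.
#' @param cellKm cell size (km).
#' @return a \linkS4class{GridSpec} whose rows/columns tile the extent.
#' @export
gridFromExtent <- function(extent, cellKm) {
  if (extent["xmax"] <= extent["xmin"] || extent["ymax"] <= extent["ymin"])
    stop("degenerate extent: zero or negative area")
  nCols <- max(1L, as.integer(round((extent["xmax"] - extent["xmin"]) / cellKm)))
  nRows <- max(1L, as.integer(round((extent["ymax"] - extent["ymin"]) / cellKm)))
  makeGrid(extent["xmin"], extent["ymax"], cellKm, nRows, nCols)
}

#' Wrap a matrix as a raster layer
#'
#' @param values numeric matrix (row 1 = north).
#' @param grid a \linkS4class{GridSpec} matching \code{dim(values)}.
#' @param name layer name.
#' @return a \linkS4class{RasterLayer}.
#' @export
rasterLayer <- function(values, grid, name = "layer") {
  new("RasterLayer", grid = grid, values = as.matrix(values), name = name)
}

#' Bundle raster layers into a stack
#'
#' @param layers named list of \linkS4class{RasterLayer} on a shared grid.
#' @return a \linkS4class{CovariateStack}.
#' @export
covariateStack <- function(layers) {
  stopifnot(length(layers) >= 1)
  new("CovariateStack", grid = layers[[1]]@grid, layers = layers)
}

#' @describeIn gridSpec grid of a raster layer
#' @export
setMethod("gridSpec", "RasterLayer", function(x) x@grid)

#' @describeIn gridSpec shared grid of a stack
#' @export
setMethod("gridSpec", "CovariateStack", function(x) x@grid)

#' @describeIn gridSpec grid of a prediction surface
#' @export
setMethod("gridSpec", "PredictionSurface", function(x) x@grid)

#' Accessors for gridded objects
#'
#' @param x the object.
#' @name gridSpec
NULL

#' Raster cell values
#'
#' @param x a RasterLayer.
#' @return the value matrix (row 1 = north).
#' @name rasterValues
NULL

#' @describeIn rasterValues value matrix of a layer
#' @export
setMethod("rasterValues", "RasterLayer", function(x) x@values)

#' Layer names of a stack
#' @param x a CovariateStack.
#' @name layerNames
NULL

#' @describeIn layerNames names of the layers
#' @export
setMethod("layerNames", "CovariateStack", function(x) names(x@layers))

#' Extract one layer from a stack
#' @param x a CovariateStack.
#' @param name layer name.
#' @name getLayer
NULL

#' @describeIn getLayer layer by name (error when absent)
#' @export
setMethod("getLayer", "CovariateStack", function(x, name) {
  if (!name %in% names(x@layers))
    stop(sprintf("missing covariate layer '%s'", name))
  x@layers[[name]]
})

#' @export
setMethod("extentOf", "GridSpec", function(x) {
  c(xmin = x@xOrigin, xmax = x@xOrigin + x@nCols * x@cellKm,
    ymin = x@yOrigin - x@nRows * x@cellKm, ymax = x@yOrigin)
})

#' @export
setMethod("extentOf", "RasterLayer", function(x) extentOf(x@grid))

#' @export
setMethod("extentOf", "CovariateStack", function(x) extentOf(x@grid))

#' @export
setMethod("extentOf", "AdminUnits", function(x) x@extent)

setMethod("show", "GridSpec", function(object) {
  e <- extentOf(object)
  cat(sprintf("GridSpec: %d x %d cells of %.3g km, x [%.6g, %.6g], y [%.6g, %.6g]\n",
              object@nRows, object@nCols, object@cellKm,
              e["xmin"], e["xmax"], e["ymin"], e["ymax"]))
})

setMethod("show", "RasterLayer", function(object) {
  v <- object@values
  cat(sprintf("RasterLayer '%s': %d x %d, range [%.4g, %.4g], %d NA\n",
              object@name, nrow(v), ncol(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  show(object@grid)
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack with %d layers: %s\n", length(object@layers),
              paste(names(object@layers), collapse = ", ")))
  show(object@grid)
})

#' Pixel-centre coordinates of a grid
#'
#' @param grid a \linkS4class{GridSpec}.
#' @return matrix with columns x, y; rows in column-major order of the value
#'   matrix, so row k matches \code{as.vector(rasterValues(layer))[k]}.
#' @export
pixelCenters <- function(grid) {
  xc <- grid@xOrigin + (seq_len(grid@nCols) - 0.5) * grid@cellKm
  yc <- grid@yOrigin - (seq_len(grid@nRows) - 0.5) * grid@cellKm
  cbind(x = rep(xc, each = grid@nRows), y = rep(yc, times = grid@nCols))
}

# Row/column of the cell containing (x, y); NA when outside the extent.
cellAt <- function(grid, x, y) {
  col <- floor((x - grid@xOrigin) / grid@cellKm) + 1
  row <- floor((grid@yOrigin - y) / grid@cellKm) + 1
  # points exactly on the south/east edge belong to the last cell
  col[x == grid@xOrigin + grid@nCols * grid@cellKm] <- grid@nCols
  row[y == grid@yOrigin - grid@nRows * grid@cellKm] <- grid@nRows
  bad <- col < 1 | col > grid@nCols | row < 1 | row > grid@nRows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Value at point locations by containing cell (no interpolation).
cellValueAt <- function(layer, x, y) {
  rc <- cellAt(layer@grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- layer@values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

# Bilinear interpolation from cell centres, edge-clamped; NA neighbours are
# dropped from the weighted mean (all-NA -> NA).
bilinearAt <- function(layer, x, y) {
  g <- layer@grid
  cx <- (x - g@xOrigin) / g@cellKm - 0.5   # fractional column - 1
  cy <- (g@yOrigin - y) / g@cellKm - 0.5   # fractional row - 1
  c0 <- pmin(pmax(floor(cx), 0), g@nCols - 1L)
  r0 <- pmin(pmax(floor(cy), 0), g@nRows - 1L)
  c1 <- pmin(c0 + 1, g@nCols - 1L)
  r1 <- pmin(r0 + 1, g@nRows - 1L)
  fx <- pmin(pmax(cx - c0, 0), 1)
  fy <- pmin(pmax(cy - r0, 0), 1)
  v <- layer@values
  idx <- function(r, c) v[cbind(r + 1L, c + 1L)]
  vals <- cbind(idx(r0, c0), idx(r0, c1), idx(r1, c0), idx(r1, c1))
  w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  w[is.na(vals)] <- 0
  vals[is.na(vals)] <- 0
  tot <- rowSums(w)
  out <- rowSums(vals * w) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Clip a raster to a rectangular extent
#'
#' Keeps the cells whose extent lies inside the clip rectangle (snapped to
#' the source grid) and updates the grid origin.
#'
#' @param src a \linkS4class{RasterLayer}.
#' @param extent named numeric (xmin, xmax, ymin, ymax), km.
#' @return the clipped \linkS4class{RasterLayer}.
#' @export
clipRaster <- function(src, extent) {
  g <- src@grid
  e <- extentOf(g)
  if (extent["xmin"] >= e["xmax"] || extent["xmax"] <= e["xmin"] ||
      extent["ymin"] >= e["ymax"] || extent["ymax"] <= e["ymin"])
    stop("clip extent is disjoint from the raster extent")
  c0 <- max(1L, as.integer(floor((extent["xmin"] - g@xOrigin) / g@cellKm + 1e-9)) + 1L)
  c1 <- min(g@nCols, as.integer(ceiling((extent["xmax"] - g@xOrigin) / g@cellKm - 1e-9)))
  r0 <- max(1L, as.integer(floor((g@yOrigin - extent["ymax"]) / g@cellKm + 1e-9)) + 1L)
  r1 <- min(g@nRows, as.integer(ceiling((g@yOrigin - extent["ymin"]) / g@cellKm - 1e-9)))
  if (c1 < c0 || r1 < r0) stop("clip produced an empty raster")
  ng <- makeGrid(g@xOrigin + (c0 - 1L) * g@cellKm,
                 g@yOrigin - (r0 - 1L) * g@cellKm,
                 g@cellKm, r1 - r0 + 1L, c1 - c0 + 1L)
  rasterLayer(src@values[r0:r1, c0:c1, drop = FALSE], ng, src@name)
}

#' Resample a raster to a target grid
#'
#' Harmonizes a source raster to the analysis grid: when the source is finer
#' than the target, each target cell gets the area-weighted mean of the
#' overlapping source cells (nodata excluded from the mean); when the source
#' is coarser, values are interpolated bilinearly from the source cell
#' centres. A source already on the target grid is returned unchanged, so
#' resampling is idempotent.
#'
#' @param src a \linkS4class{RasterLayer}.
#' @param target a \linkS4class{GridSpec}; its extent must overlap the source.
#' @return a \linkS4class{RasterLayer} on \code{target}.
#' @export
resampleToGrid <- function(src, target) {
  g <- src@grid
  es <- extentOf(g); et <- extentOf(target)
  if (et["xmin"] >= es["xmax"] || et["xmax"] <= es["xmin"] ||
      et["ymin"] >= es["ymax"] || et["ymax"] <= es["ymin"])
    stop("source and target extents are disjoint")
  if (sameGrid(g, target)) return(rasterLayer(src@values, target, src@name))
  if (target@cellKm > g@cellKm * (1 + 1e-9)) {
    out <- aggregateAreaWeighted(src, target)
  } else {
    pc <- pixelCenters(target)
    inside <- pc[, "x"] >= es["xmin"] & pc[, "x"] <= es["xmax"] &
      pc[, "y"] >= es["ymin"] & pc[, "y"] <= es["ymax"]
    vals <- rep(NA_real_, nrow(pc))
    vals[inside] <- bilinearAt(src, pc[inside, "x"], pc[inside, "y"])
    out <- matrix(vals, target@nRows, target@nCols)
  }
  rasterLayer(out, target, src@name)
}

# Area-weighted aggregation onto a coarser grid. Per-axis overlap weights
# between target and source cell intervals are precomputed, then combined.
aggregateAreaWeighted <- function(src, target) {
  g <- src@grid
  axisOverlap <- function(t0, cell_t, n_t, s0, cell_s, n_s, descending) {
    # returns list over target index: source indices + overlap lengths
    lapply(seq_len(n_t), function(i) {
      if (descending) { a <- t0 - i * cell_t; b <- t0 - (i - 1) * cell_t }
      else { a <- t0 + (i - 1) * cell_t; b <- t0 + i * cell_t }
      if (descending) {
        j0 <- max(1L, floor((s0 - b) / cell_s) + 1L)
        j1 <- min(n_s, ceiling((s0 - a) / cell_s))
        if (j1 < j0) return(list(idx = integer(), w = numeric()))
        js <- j0:j1
        lo <- s0 - js * cell_s; hi <- s0 - (js - 1) * cell_s
      } else {
        j0 <- max(1L, floor((a - s0) / cell_s) + 1L)
        j1 <- min(n_s, ceiling((b - s0) / cell_s))
        if (j1 < j0) return(list(idx = integer(), w = numeric()))
        js <- j0:j1
        lo <- s0 + (js - 1) * cell_s; hi <- s0 + js * cell_s
      }
      w <- pmax(0, pmin(hi, b) - pmax(lo, a))
      keep <- w > 1e-12
      list(idx = js[keep], w = w[keep])
    })
  }
  colW <- axisOverlap(target@xOrigin, target@cellKm, target@nCols,
                      g@xOrigin, g@cellKm, g@nCols, descending = FALSE)
  rowW <- axisOverlap(target@yOrigin, target@cellKm, target@nRows,
                      g@yOrigin, g@cellKm, g@nRows, descending = TRUE)
  v <- src@values
  out <- matrix(NA_real_, target@nRows, target@nCols)
  for (R in seq_len(target@nRows)) {
    rw <- rowW[[R]]
    if (!length(rw$idx)) next
    for (C in seq_len(target@nCols)) {
      cw <- colW[[C]]
      if (!length(cw$idx)) next
      block <- v[rw$idx, cw$idx, drop = FALSE]
      W <- outer(rw$w, cw$w)
      W[is.na(block)] <- 0
      tw <- sum(W)
      if (tw > 0) out[R, C] <- sum(block * W, na.rm = TRUE) / tw
    }
  }
  out
}

#' Read / write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster interchange (.asc): a six-line header
#' (NCOLS, NROWS, XLLCORNER, YLLCORNER, CELLSIZE, NODATA_value) followed by
#' rows of values, north row first. Coordinates are km here.
#'
#' @param path file path.
#' @param layer a \linkS4class{RasterLayer} (for writing).
#' @param name layer name to attach on read.
#' @param nodata nodata sentinel written for \code{NA} cells.
#' @return \code{readAsciiGrid} returns a \linkS4class{RasterLayer};
#'   \code{writeAsciiGrid} returns \code{path} invisibly.
#' @export
writeAsciiGrid <- function(layer, path, nodata = -9999) {
  g <- layer@grid
  v <- layer@values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("NCOLS %d", g@nCols), sprintf("NROWS %d", g@nRows),
           sprintf("XLLCORNER %.10g", g@xOrigin),
           sprintf("YLLCORNER %.10g", g@yOrigin - g@nRows * g@cellKm),
           sprintf("CELLSIZE %.10g", g@cellKm),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path, name = sub("[.][^.]*$", "", basename(path))) {
  ln <- readLines(path)
  if (length(ln) < 7) stop(sprintf("'%s': not an ASCII grid (too short)", path))
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(ln[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2)
      stop(sprintf("'%s' line %d: malformed header '%s'", path, i, ln[i]))
    hdr[[toupper(parts[1])]] <- as.numeric(parts[2])
  }
  nCols <- as.integer(hdr$NCOLS); nRows <- as.integer(hdr$NROWS)
  vals <- scan(text = paste(ln[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nRows * nCols)
    stop(sprintf("'%s': expected %d values, found %d", path,
                 nRows * nCols, length(vals)))
  v <- matrix(vals, nRows, nCols, byrow = TRUE)
  v[v == hdr$NODATA_VALUE] <- NA_real_
  g <- makeGrid(hdr$XLLCORNER, hdr$YLLCORNER + nRows * hdr$CELLSIZE,
                hdr$CELLSIZE, nRows, nCols)
  rasterLayer(v, g, name)
}
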