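#' Configure the synthetic survey world
#'
#' Builds the configuration for the seeded generator that emulates the data
#' a DHS-style fertility analysis consumes: a two-stage stratified cluster
#' sample with sampling weights, women's birth histories whose age-specific
#' rates follow a latent spatial surface, smooth covariate rasters on a
#' kilometre grid, and nested admin units. Defaults describe a 100 x 100 km
#' region with 250 clusters of 25 women, fixed effects of the magnitudes
#' reported for fertility covariates (per standard deviation of each
#' covariate), a Matern latent field, and a base age-specific fertility
#' schedule summing to TFR 4.5 / 5.
#'
#' @param extent named numeric (xmin, xmax, ymin, ymax), km.
#' @param cellKm grid resolution, km.
#' @param nClusters number of survey clusters.
#' @param urbanFraction proportion of clusters flagged urban.
#' @param womenPerCluster women interviewed per cluster.
#' @param trueBeta named fixed effects on the TFR scale per covariate SD;
#'   names must match covariate layers.
#' @param trueIntercept intercept on the TFR scale (the base TFR).
#' @param matern \linkS4class{MaternParams} of the latent TFR field.
#' @param baseAsfr 7 nonnegative base rates (births per woman-year) for ages
#'   15-19 ... 45-49; their sum times 5 is the base TFR of the schedule.
#' @param nCities,nFacilities seeded point sets behind the distance layers.
#' @param surveyYear calendar year of the survey round.
#' @param seed master seed; every generator stage derives a named substream
#'   from it, so identical config + seed gives byte-identical output.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(extent = c(xmin = 0, xmax = 100, ymin = 0, ymax = 100),
                             cellKm = 1,
                             nClusters = 250,
                             urbanFraction = 0.2,
                             womenPerCluster = 25,
                             trueBeta = c(travel_time_city = 0.42,
                                          dist_health_facility = 0.17,
                                          altitude = 0.14,
                                          pop_density = -0.01,
                                          prop_muslim = 0.37),
                             trueIntercept = 4.5,
                             matern = maternParams(sigma2 = 0.5, rangeKm = 30, nu = 1),
                             baseAsfr = c(0.10, 0.20, 0.21, 0.17, 0.12, 0.07, 0.03),
                             nCities = 5, nFacilities = 40,
                             surveyYear = 2016, seed = 1) {
  new("SimulationConfig", extent = extent, cellKm = as.numeric(cellKm),
      nClusters = as.integer(nClusters),
      urbanFraction = as.numeric(urbanFraction),
      womenPerCluster = as.integer(womenPerCluster),
      trueBeta = trueBeta, trueIntercept = as.numeric(trueIntercept),
      matern = matern, baseAsfr = as.numeric(baseAsfr),
      nCities = as.integer(nCities), nFacilities = as.integer(nFacilities),
      surveyYear = as.integer(surveyYear), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  e <- object@extent
  cat(sprintf("SimulationConfig: %g x %g km at %g km, %d clusters x %d women, seed %d\n",
              e["xmax"] - e["xmin"], e["ymax"] - e["ymin"], object@cellKm,
              object@nClusters, object@womenPerCluster, object@seed))
  cat(sprintf("  base TFR %.2f (schedule sum %.3f), intercept %.2f, urban fraction %.2f\n",
              5 * sum(object@baseAsfr), sum(object@baseAsfr),
              object@trueIntercept, object@urbanFraction))
})

# Seeded point sets driving the distance covariates and the urban strata.
# Points are snapped to pixel centres so a distance layer is exactly zero
# at the pixel holding the point.
seededPoints <- function(config, n, stream) {
  grid <- gridFromExtent(config@extent, config@cellKm)
  withSeed(substreamSeed(config@seed, stream), {
    e <- config@extent
    x <- runif(n, e["xmin"], e["xmax"])
    y <- runif(n, e["ymin"], e["ymax"])
  })
  rc <- cellAt(grid, x, y)
  cbind(x = grid@xOrigin + (rc[, "col"] - 0.5) * grid@cellKm,
        y = grid@yOrigin - (rc[, "row"] - 0.5) * grid@cellKm)
}

cityPoints <- function(config) seededPoints(config, config@nCities, "cities")

facilityPoints <- function(config)
  seededPoints(config, config@nFacilities, "facilities")

minDistTo <- function(px, py, points) {
  d2 <- outer(px, points[, "x"], "-")^2 + outer(py, points[, "y"], "-")^2
  sqrt(apply(d2, 1, min))
}

# Smooth random surface: iid Gaussian noise on a coarse lattice, bilinearly
# refined to the target grid.
smoothSurface <- function(grid, coarse_km, seed, sd = 1) {
  e <- extentOf(grid)
  cg <- gridFromExtent(e, coarse_km)
  withSeed(seed, {
    z <- matrix(rnorm(cg@nRows * cg@nCols, 0, sd), cg@nRows, cg@nCols)
  })
  resampleToGrid(rasterLayer(z, cg, "smooth"), grid)
}

#' Simulate the covariate rasters
#'
#' One layer per covariate on the configured grid: travel time to city and
#' distance to health facility are Euclidean distances (km) to seeded point
#' sets; altitude is a smoothed random surface around 1500 m; population
#' density is a log-Gaussian surface concentrated near cities (strictly
#' positive).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{CovariateStack} with layers travel_time_city,
#'   dist_health_facility, altitude, pop_density.
#' @export
simulateCovariateRasters <- function(config) {
  validObject(config)
  grid <- gridFromExtent(config@extent, config@cellKm)
  pc <- pixelCenters(grid)
  cities <- cityPoints(config)
  facilities <- facilityPoints(config)
  dcity <- matrix(minDistTo(pc[, "x"], pc[, "y"], cities),
                  grid@nRows, grid@nCols)
  dfac <- matrix(minDistTo(pc[, "x"], pc[, "y"], facilities),
                 grid@nRows, grid@nCols)
  diag_km <- sqrt(sum((config@extent[c("xmax", "ymax")] -
                       config@extent[c("xmin", "ymin")])^2))
  coarse <- max(4 * config@cellKm, diag_km / 25)
  alt <- smoothSurface(grid, coarse, substreamSeed(config@seed, "altitude"))
  altitude <- 1500 + 400 * alt@values
  popsm <- smoothSurface(grid, coarse, substreamSeed(config@seed, "popdensity"))
  pop_density <- exp(4 + 0.9 * popsm@values - 0.015 * dcity)
  covariateStack(list(
    travel_time_city = rasterLayer(dcity, grid, "travel_time_city"),
    dist_health_facility = rasterLayer(dfac, grid, "dist_health_facility"),
    altitude = rasterLayer(altitude, grid, "altitude"),
    pop_density = rasterLayer(pop_density, grid, "pop_density")))
}

#' Simulate one draw of a Matern Gaussian field
#'
#' Draws a zero-mean Gaussian random field with Matern covariance on the
#' grid by dense Cholesky factorization of the covariance over a coarsened
#' lattice (at most 50 x 50 nodes), then bilinear refinement to the full
#' grid. Exact at the coarse nodes; between nodes the interpolation slightly
#' smooths the field, which is negligible when the range is much larger than
#' the coarse spacing.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param params \linkS4class{MaternParams}; \code{sigma2 = 0} returns the
#'   zero field.
#' @param seed integer seed.
#' @return a \linkS4class{RasterLayer} named "matern_field".
#' @export
simulateMaternField <- function(grid, params, seed) {
  validObject(params)
  if (params@sigma2 == 0)
    return(rasterLayer(matrix(0, grid@nRows, grid@nCols), grid, "matern_field"))
  e <- extentOf(grid)
  span <- max(e["xmax"] - e["xmin"], e["ymax"] - e["ymin"])
  coarse_km <- max(grid@cellKm, span / 50)
  cg <- gridFromExtent(e, coarse_km)
  coords <- pixelCenters(cg)
  L <- cachedFieldChol(coords, params)
  z <- withSeed(seed, rnorm(nrow(coords)))
  draw <- as.vector(crossprod(L, z))
  coarse <- rasterLayer(matrix(draw, cg@nRows, cg@nCols), cg, "matern_field")
  if (sameGrid(cg, grid)) coarse else resampleToGrid(coarse, grid)
}

#' Simulate survey clusters
#'
#' Places clusters uniformly over the extent; the \code{round(urbanFraction
#' * n)} clusters nearest to the seeded city points are flagged urban. Each
#' stratum gets a design weight (urban 0.8, rural 1.25 before scaling),
#' normalized so the mean weight over clusters is exactly 1.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame: cluster_id, x_km, y_km, urban (0/1), year, weight.
#' @export
simulateClusters <- function(config) {
  validObject(config)
  grid <- gridFromExtent(config@extent, config@cellKm)
  if (config@nClusters > grid@nRows * grid@nCols)
    stop(sprintf("n_clusters (%d) exceeds the number of grid cells (%d)",
                 config@nClusters, grid@nRows * grid@nCols))
  e <- config@extent
  n <- config@nClusters
  xy <- withSeed(substreamSeed(config@seed, "clusters"), {
    cbind(x = runif(n, e["xmin"], e["xmax"]),
          y = runif(n, e["ymin"], e["ymax"]))
  })
  dcity <- minDistTo(xy[, "x"], xy[, "y"], cityPoints(config))
  nUrban <- round(config@urbanFraction * n)
  urban <- integer(n)
  if (nUrban > 0) urban[order(dcity)[seq_len(nUrban)]] <- 1L
  w <- ifelse(urban == 1L, 0.8, 1.25)
  w <- w / mean(w)
  data.frame(cluster_id = sprintf("c%04d", seq_len(n)),
             x_km = xy[, "x"], y_km = xy[, "y"], urban = urban,
             year = config@surveyYear, weight = w,
             stringsAsFactors = FALSE)
}

#' Latent proportion-Muslim surface
#'
#' A smooth probability surface on the grid: the logistic transform of a
#' Matern latent field around a logit baseline of 0.35. This is the true
#' religious-composition surface the generator uses; cluster-level observed
#' proportions are binomial draws from it (see
#' \code{simulateClusterProportions}).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{RasterLayer} named "prop_muslim" with values in
#'   (0, 1).
#' @export
simulateReligionSurface <- function(config) {
  grid <- gridFromExtent(config@extent, config@cellKm)
  fld <- simulateMaternField(grid,
                             maternParams(sigma2 = 1.5, rangeKm = 40, nu = 1),
                             substreamSeed(config@seed, "religion"))
  p <- stats::plogis(stats::qlogis(0.35) + fld@values)
  rasterLayer(p, grid, "prop_muslim")
}

#' Observed cluster proportions from the latent religion surface
#'
#' @param clusters cluster data.frame from \code{simulateClusters}.
#' @param surface latent surface from \code{simulateReligionSurface}.
#' @param config the \linkS4class{SimulationConfig}.
#' @return data.frame: cluster_id, x_km, y_km, proportion (binomial draw of
#'   womenPerCluster trials at the local true proportion), n_women.
#' @export
simulateClusterProportions <- function(clusters, surface, config) {
  p <- cellValueAt(surface, clusters$x_km, clusters$y_km)
  nw <- config@womenPerCluster
  obs <- withSeed(substreamSeed(config@seed, "religion-sampling"),
                  rbinom(nrow(clusters), nw, p)) / nw
  data.frame(cluster_id = clusters$cluster_id, x_km = clusters$x_km,
             y_km = clusters$y_km, proportion = obs, n_women = nw,
             stringsAsFactors = FALSE)
}

# True local TFR surface values at arbitrary points: intercept + sum of
# standardized-covariate effects + latent field, floored at 0.2.
trueTfrAt <- function(x, y, stack, field, config) {
  lp <- rep(config@trueIntercept, length(x))
  for (nm in names(config@trueBeta)) {
    ly <- getLayer(stack, nm)
    v <- ly@values
    mu <- mean(v, na.rm = TRUE); s <- sd(as.vector(v), na.rm = TRUE)
    z <- (cellValueAt(ly, x, y) - mu) / s
    lp <- lp + config@trueBeta[[nm]] * z
  }
  lp <- lp + cellValueAt(field, x, y)
  pmax(lp, 0.2)
}

#' Simulate women's birth histories
#'
#' The generative counterpart of the fitted model: each cluster's local true
#' TFR is the intercept plus standardized-covariate effects plus the latent
#' Matern field, floored at 0.2. Women are assigned an age at interview
#' uniform on [15, 50) years (whole months, CMC convention); over the
#' 36-month window before interview each age-group segment of a woman's
#' exposure generates a Poisson number of births with rate
#' \code{exposure_years * baseAsfr[a] * TFR(s) / TFR_base}, and birth months
#' are placed uniformly within the segment.
#'
#' @param clusters data.frame from \code{simulateClusters}.
#' @param stack \linkS4class{CovariateStack} containing every layer named in
#'   \code{trueBeta} (covariates are standardized over pixels before the
#'   effects apply).
#' @param field latent \linkS4class{RasterLayer} from
#'   \code{simulateMaternField}.
#' @param config the \linkS4class{SimulationConfig}.
#' @param windowMonths exposure window length (months before interview).
#' @return data.frame: woman_id, cluster_id, dob_cmc, doi_cmc, weight, and
#'   list-column child_dobs_cmc of birth months.
#' @export
simulateBirthHistories <- function(clusters, stack, field, config,
                                   windowMonths = 36L) {
  for (nm in names(config@trueBeta))
    getLayer(stack, nm)  # errors naming any missing layer
  tfr_s <- trueTfrAt(clusters$x_km, clusters$y_km, stack, field, config)
  tfr_base <- 5 * sum(config@baseAsfr)
  nw <- config@womenPerCluster
  nWomen <- nrow(clusters) * nw
  doi <- (config@surveyYear - 1900L) * 12L + 6L  # CMC of the interview month
  withSeed(substreamSeed(config@seed, "women"), {
    ageMonths <- 180L + as.integer(floor(runif(nWomen) * 420))
    dob <- doi - ageMonths
    clusterIdx <- rep(seq_len(nrow(clusters)), each = nw)
    rate_scale <- tfr_s[clusterIdx] / tfr_base
    a0 <- (doi - windowMonths + 1L) - dob        # age at first window month
    childList <- vector("list", nWomen)
    for (g in 1:7) {
      glo <- 180L + 60L * (g - 1L); ghi <- glo + 59L
      lo <- pmax(a0, glo); hi <- pmin(a0 + windowMonths - 1L, ghi)
      months <- pmax(0L, hi - lo + 1L)
      lam <- (months / 12) * config@baseAsfr[g] * rate_scale
      nb <- rpois(nWomen, lam)
      has <- which(nb > 0L)
      for (i in has) {
        ages <- lo[i] + as.integer(floor(runif(nb[i]) * months[i]))
        childList[[i]] <- c(childList[[i]], dob[i] + ages)
      }
    }
    childList <- lapply(childList, function(x) if (is.null(x)) integer() else sort(x))
    out <- data.frame(
      woman_id = sprintf("w%06d", seq_len(nWomen)),
      cluster_id = clusters$cluster_id[clusterIdx],
      dob_cmc = dob, doi_cmc = rep(doi, nWomen),
      weight = clusters$weight[clusterIdx], stringsAsFactors = FALSE)
    out$child_dobs_cmc <- childList
    out
  })
}

#' Simulate nested administrative units
#'
#' Partitions the extent into rectangular regions, zones within regions and
#' districts within zones, with break lines snapped to the grid so every
#' pixel belongs to exactly one unit per level. Child units carry parent
#' IDs.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param nRegions regions tiling the extent (vertical strips).
#' @param nZonesPerRegion zones per region (horizontal strips).
#' @param nDistrictsPerZone districts per zone (vertical strips).
#' @param seed integer seed for the break positions.
#' @return an \linkS4class{AdminUnits} object.
#' @export
simulateAdminUnits <- function(grid, nRegions, nZonesPerRegion = 2L,
                               nDistrictsPerZone = 2L, seed = 1L) {
  stopifnot(nRegions >= 1, nZonesPerRegion >= 1, nDistrictsPerZone >= 1)
  e <- extentOf(grid)
  # n breaks snapped to interior grid lines: near-equal strips with a
  # seeded +/-1-cell jitter, each strip kept at least minCells wide so
  # child levels can subdivide it. Errors when the partition would be
  # finer than the grid.
  cutLines <- function(lo, hi, n, cell, minCells = 1L) {
    nCells <- round((hi - lo) / cell)
    if (n * minCells > nCells)
      stop("admin partition finer than the grid")
    if (n == 1) return(c(lo, hi))
    ix <- round(seq_len(n - 1L) / n * nCells)
    jit <- sample(c(-1L, 0L, 1L), n - 1L, replace = TRUE)
    cand <- ix + jit
    parts <- diff(c(0L, cand, nCells))
    if (all(parts >= minCells)) ix <- cand
    c(lo, lo + ix * cell, hi)
  }
  withSeed(seed, {
    units <- list()
    rx <- cutLines(e["xmin"], e["xmax"], nRegions, grid@cellKm,
                   minCells = as.integer(nDistrictsPerZone))
    for (r in seq_len(nRegions)) {
      rid <- sprintf("R%02d", r)
      units[[length(units) + 1L]] <- data.frame(
        id = rid, level = "region", parent_id = "national",
        xmin = rx[r], xmax = rx[r + 1], ymin = e["ymin"], ymax = e["ymax"],
        stringsAsFactors = FALSE)
      zy <- cutLines(e["ymin"], e["ymax"], nZonesPerRegion, grid@cellKm)
      for (z in seq_len(nZonesPerRegion)) {
        zid <- sprintf("%sZ%02d", rid, z)
        units[[length(units) + 1L]] <- data.frame(
          id = zid, level = "zone", parent_id = rid,
          xmin = rx[r], xmax = rx[r + 1], ymin = zy[z], ymax = zy[z + 1],
          stringsAsFactors = FALSE)
        dx <- cutLines(rx[r], rx[r + 1], nDistrictsPerZone, grid@cellKm)
        for (d in seq_len(nDistrictsPerZone)) {
          did <- sprintf("%sD%02d", zid, d)
          units[[length(units) + 1L]] <- data.frame(
            id = did, level = "district", parent_id = zid,
            xmin = dx[d], xmax = dx[d + 1], ymin = zy[z], ymax = zy[z + 1],
            stringsAsFactors = FALSE)
        }
      }
    }
    new("AdminUnits", units = do.call(rbind, units), extent = e)
  })
}

setMethod("show", "AdminUnits", function(object) {
  tab <- table(object@units$level)
  cat(sprintf("AdminUnits: %s\n",
              paste(sprintf("%d %ss", as.integer(tab), names(tab)),
                    collapse = ", ")))
})
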