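#' @import methods
#' @importFrom stats approx cor dlnorm dnorm optimize pnorm qnorm quantile
#'   rbinom rnorm rpois runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

#' Grid specification for a raster on a projected kilometre plane
#'
#' Defines a regular grid by its north-west corner, square cell size and
#' dimensions. Row 1 is the northmost row; the centre of pixel (r, c) is
#' \code{(xOrigin + (c - 0.5) * cellKm, yOrigin - (r - 0.5) * cellKm)}.
#' All coordinates are in kilometres on a flat projected plane.
#'
#' @slot xOrigin x coordinate (km) of the west edge.
#' @slot yOrigin y coordinate (km) of the north edge.
#' @slot cellKm cell size in km (> 0).
#' @slot nRows,nCols grid dimensions.
#' @export
setClass("GridSpec",
  representation(xOrigin = "numeric", yOrigin = "numeric",
                 cellKm = "numeric", nRows = "integer", nCols = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@cellKm) != 1 || !is.finite(object@cellKm) ||
        object@cellKm <= 0)
      msg <- c(msg, "cellKm must be a single positive number")
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "nRows and nCols must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Single-band raster layer
#'
#' A numeric matrix bound to a \linkS4class{GridSpec}. Missing cells are
#' stored as \code{NA}; the nodata sentinel (-9999 by default) is only used
#' on disk.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot values numeric matrix, \code{nRows x nCols}, row 1 = north.
#' @slot name layer name.
#' @export
setClass("RasterLayer",
  representation(grid = "GridSpec", values = "matrix", name = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (d[1] != object@grid@nRows || d[2] != object@grid@nCols)
      return("values matrix does not match grid dimensions")
    TRUE
  })

#' Named set of raster layers sharing one grid
#'
#' @slot grid the shared \linkS4class{GridSpec}.
#' @slot layers named list of \linkS4class{RasterLayer}, all on \code{grid}.
#' @export
setClass("CovariateStack",
  representation(grid = "GridSpec", layers = "list"),
  validity = function(object) {
    if (length(object@layers) == 0) return("stack has no layers")
    if (is.null(names(object@layers)) || any(!nzchar(names(object@layers))))
      return("all layers must be named")
    for (nm in names(object@layers)) {
      ly <- object@layers[[nm]]
      if (!is(ly, "RasterLayer"))
        return(sprintf("layer '%s' is not a RasterLayer", nm))
      if (!identical(unname(gridKey(ly@grid)), unname(gridKey(object@grid))))
        return(sprintf("layer '%s' is not on the shared grid", nm))
    }
    TRUE
  })

#' Matern covariance hyperparameters
#'
#' Parameterized so that \code{rangeKm} is the distance at which correlation
#' drops to about 0.1 (the kappa = sqrt(8 nu) / range convention).
#'
#' @slot sigma2 partial sill (field variance), > 0.
#' @slot rangeKm spatial range in km, > 0.
#' @slot nu smoothness, > 0.
#' @slot nugget iid variance component, >= 0.
#' @export
setClass("MaternParams",
  representation(sigma2 = "numeric", rangeKm = "numeric",
                 nu = "numeric", nugget = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@sigma2 < 0) msg <- c(msg, "sigma2 must be >= 0")
    if (object@rangeKm <= 0) msg <- c(msg, "rangeKm must be > 0")
    if (object@nu <= 0) msg <- c(msg, "nu must be > 0")
    if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Configuration of the synthetic survey world
#'
#' Bundles everything the generator needs: the region extent, grid
#' resolution, survey design sizes, the true fixed effects on standardized
#' covariates, the latent Matern field, and the base age-specific fertility
#' schedule (births per woman-year for the seven 5-year groups 15-49, which
#' sum to TFR_base / 5).
#'
#' @slot extent named numeric (xmin, xmax, ymin, ymax) in km.
#' @slot cellKm grid resolution in km.
#' @slot nClusters number of survey clusters.
#' @slot urbanFraction proportion of clusters flagged urban, in [0, 1].
#' @slot womenPerCluster women interviewed per cluster.
#' @slot trueBeta named vector of fixed-effect coefficients on the TFR scale
#'   per standard deviation of each covariate.
#' @slot trueIntercept intercept on the TFR scale.
#' @slot matern \linkS4class{MaternParams} of the latent spatial field
#'   (nugget unused by the generator).
#' @slot baseAsfr the 7 base age-specific rates (births per woman-year).
#' @slot nCities,nFacilities numbers of seeded city / health-facility points.
#' @slot surveyYear calendar year stamped on clusters.
#' @slot seed integer master seed; all generator randomness derives from it.
#' @export
setClass("SimulationConfig",
  representation(extent = "numeric", cellKm = "numeric",
                 nClusters = "integer", urbanFraction = "numeric",
                 womenPerCluster = "integer", trueBeta = "numeric",
                 trueIntercept = "numeric", matern = "MaternParams",
                 baseAsfr = "numeric", nCities = "integer",
                 nFacilities = "integer", surveyYear = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    e <- object@extent
    if (length(e) != 4 || !all(c("xmin", "xmax", "ymin", "ymax") %in% names(e)))
      msg <- c(msg, "extent must be named (xmin, xmax, ymin, ymax)")
    else if (e["xmax"] <= e["xmin"] || e["ymax"] <= e["ymin"])
      msg <- c(msg, "degenerate extent: zero or negative area")
    if (object@urbanFraction < 0 || object@urbanFraction > 1)
      msg <- c(msg, "urbanFraction must lie in [0, 1]")
    if (object@nClusters < 1L || object@womenPerCluster < 1L ||
        object@nCities < 1L || object@nFacilities < 1L)
      msg <- c(msg, "all counts must be >= 1")
    if (length(object@baseAsfr) != 7 || any(object@baseAsfr < 0))
      msg <- c(msg, "baseAsfr must be 7 nonnegative rates")
    if (length(msg)) msg else TRUE
  })

#' Age-specific and total fertility rates over seven 5-year age groups
#'
#' Weighted births, woman-years of exposure and rates for the groups
#' [15,20), ..., [45,50), with TFR = 5 * sum(ASFR). Groups with zero
#' exposure get ASFR 0 and clear the \code{complete} flag instead of
#' propagating NaN.
#'
#' @slot births,exposure,asfr numeric(7); exposure in woman-years.
#' @slot tfr total fertility rate.
#' @slot complete TRUE when every group had positive exposure.
#' @slot droppedBirths births to mothers outside ages [15, 50) at delivery,
#'   excluded from the numerators (diagnostic tally, weighted).
#' @export
setClass("AgeGroupRates",
  representation(births = "numeric", exposure = "numeric", asfr = "numeric",
                 tfr = "numeric", complete = "logical",
                 droppedBirths = "numeric"),
  validity = function(object) {
    if (length(object@births) != 7 || length(object@exposure) != 7 ||
        length(object@asfr) != 7)
      return("births, exposure and asfr must have length 7")
    TRUE
  })

#' Nested rectangular administrative units
#'
#' Regions tile the extent, zones tile each region, districts tile each
#' zone; every location belongs to exactly one unit per level and child
#' units carry their parent IDs.
#'
#' @slot units data.frame with columns id, level (region | zone | district),
#'   parent_id, xmin, xmax, ymin, ymax.
#' @slot extent named numeric (xmin, xmax, ymin, ymax).
#' @export
setClass("AdminUnits",
  representation(units = "data.frame", extent = "numeric"),
  validity = function(object) {
    need <- c("id", "level", "parent_id", "xmin", "xmax", "ymin", "ymax")
    if (!all(need %in% names(object@units)))
      return(paste("units must have columns", paste(need, collapse = ", ")))
    if (!all(object@units$level %in% c("region", "zone", "district")))
      return("level must be region, zone or district")
    TRUE
  })

#' Standardized design matrix with its standardization record
#'
#' One row per cluster, one column per covariate layer; each column is
#' centred and scaled to unit variance and the constants are kept so the
#' same transform can be replayed on prediction rasters.
#'
#' @slot X standardized matrix.
#' @slot center,scale named per-column standardization constants.
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", center = "numeric", scale = "numeric"),
  validity = function(object) {
    if (ncol(object@X) != length(object@center) ||
        ncol(object@X) != length(object@scale))
      return("center/scale length must match the number of columns")
    TRUE
  })

#' Bayesian kriging fit of a cluster-level proportion
#'
#' Holds the data, the prior mean, and the hyperparameter grid with
#' normalized posterior weights (likelihood times independent log-normal
#' priors, smoothness fixed).
#'
#' @slot x,y,z data locations (km) and observed proportions.
#' @slot mu0 prior mean (weighted mean of the observations).
#' @slot nu fixed Matern smoothness.
#' @slot nodes data.frame sigma2, rangeKm, nugget, logLik, logPrior, weight.
#' @export
setClass("KrigeFit",
  representation(x = "numeric", y = "numeric", z = "numeric",
                 mu0 = "numeric", nu = "numeric", nodes = "data.frame"),
  validity = function(object) {
    if (abs(sum(object@nodes$weight) - 1) > 1e-8)
      return("node weights must sum to 1")
    TRUE
  })

#' Geostatistical model fit (Gaussian GAM + optional Matern field)
#'
#' Per hyperparameter node the posterior of all coefficients is exactly
#' Gaussian; node weights are proportional to the marginal likelihood under
#' a flat prior on the grid. Summaries are weighted-mixture moments and
#' quantiles.
#'
#' @slot y response vector (cluster TFR or summed ASFR).
#' @slot X standardized design matrix including the intercept column.
#' @slot locations n x 2 matrix of cluster coordinates (km).
#' @slot spatial TRUE when the Matern random effect is included.
#' @slot priorSdBeta sd of the mean-zero Gaussian prior on fixed effects.
#' @slot nu fixed Matern smoothness.
#' @slot smooth list describing smooth terms (empty when none).
#' @slot nodes data.frame of hyper nodes: sigma2, rangeKm, nugget, logML,
#'   weight.
#' @slot summaryTable data.frame term, mean, sd, lower95, upper95.
#' @slot logML mixed log marginal likelihood (model evidence on the grid).
#' @export
setClass("GeostatFit",
  representation(y = "numeric", X = "matrix", locations = "matrix",
                 spatial = "logical", priorSdBeta = "numeric",
                 nu = "numeric", smooth = "list", nodes = "data.frame",
                 summaryTable = "data.frame", logML = "numeric"),
  validity = function(object) {
    if (abs(sum(object@nodes$weight) - 1) > 1e-8)
      return("node weights must sum to 1")
    st <- object@summaryTable
    if (nrow(st) && any(st$lower95 > st$mean + 1e-9 |
                        st$mean > st$upper95 + 1e-9))
      return("summary quantiles must bracket the mean")
    TRUE
  })

#' Posterior prediction surface
#'
#' Pixel-level posterior mean, sd and 95% credible bounds on a shared grid.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot mean,sd,lower95,upper95 numeric matrices on the grid.
#' @export
setClass("PredictionSurface",
  representation(grid = "GridSpec", mean = "matrix", sd = "matrix",
                 lower95 = "matrix", upper95 = "matrix"),
  validity = function(object) {
    ok <- function(m) identical(dim(m), c(object@grid@nRows, object@grid@nCols))
    if (!ok(object@mean) || !ok(object@sd) || !ok(object@lower95) ||
        !ok(object@upper95))
      return("surface matrices must match the grid")
    bad <- which(object@lower95 > object@mean + 1e-9 |
                 object@mean > object@upper95 + 1e-9)
    if (length(bad)) return("lower95 <= mean <= upper95 must hold pixelwise")
    if (any(object@sd < -1e-12, na.rm = TRUE)) return("sd must be >= 0")
    TRUE
  })
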