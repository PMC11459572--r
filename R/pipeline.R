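# Format readers/writers and the end-to-end orchestrated run.

#' Read and write the women (birth history) table
#'
#' CSV schema: woman_id, cluster_id, dob_cmc, doi_cmc, weight,
#' child_dobs_cmc — the last a semicolon-separated list of birth months
#' (empty for childless women).
#'
#' @param women women data.frame with list-column child_dobs_cmc.
#' @param path file path.
#' @return \code{readWomenCsv} returns the data.frame with the list-column
#'   restored.
#' @export
writeWomenCsv <- function(women, path) {
  out <- women[, c("woman_id", "cluster_id", "dob_cmc", "doi_cmc", "weight")]
  out$child_dobs_cmc <- vapply(women$child_dobs_cmc, paste,
                               character(1), collapse = ";")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeWomenCsv
#' @export
readWomenCsv <- function(path) {
  df <- read.csv(path, colClasses = c(
    woman_id = "character", cluster_id = "character", dob_cmc = "integer",
    doi_cmc = "integer", weight = "numeric", child_dobs_cmc = "character"))
  df$child_dobs_cmc <- lapply(strsplit(df$child_dobs_cmc, ";", fixed = TRUE),
                              function(x) as.integer(x[nzchar(x)]))
  df
}

#' Read and write the cluster table
#'
#' CSV schema: cluster_id, x_km, y_km, urban (0/1), year, weight.
#' @param clusters cluster data.frame.
#' @param path file path.
#' @export
writeClustersCsv <- function(clusters, path) {
  write.csv(clusters, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeClustersCsv
#' @export
readClustersCsv <- function(path) {
  read.csv(path, colClasses = c(
    cluster_id = "character", x_km = "numeric", y_km = "numeric",
    urban = "integer", year = "integer", weight = "numeric"))
}

#' Read and write admin units as GeoJSON
#'
#' Each unit becomes a Polygon feature with properties id, level and
#' parent_id; rectangles are closed rings in (x, y) km coordinates.
#'
#' @param admin an \linkS4class{AdminUnits} object.
#' @param path file path.
#' @export
writeAdminGeoJSON <- function(admin, path) {
  features <- lapply(seq_len(nrow(admin@units)), function(i) {
    u <- admin@units[i, ]
    ring <- list(c(u$xmin, u$ymin), c(u$xmax, u$ymin), c(u$xmax, u$ymax),
                 c(u$xmin, u$ymax), c(u$xmin, u$ymin))
    list(type = "Feature",
         properties = list(id = u$id, level = u$level,
                           parent_id = u$parent_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeAdminGeoJSON
#' @export
readAdminGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop(sprintf("'%s': not a GeoJSON FeatureCollection", path))
  units <- do.call(rbind, lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    data.frame(id = f$properties$id, level = f$properties$level,
               parent_id = if (is.null(f$properties$parent_id)) NA_character_
                           else f$properties$parent_id,
               xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys),
               stringsAsFactors = FALSE)
  }))
  ext <- c(xmin = min(units$xmin), xmax = max(units$xmax),
           ymin = min(units$ymin), ymax = max(units$ymax))
  new("AdminUnits", units = units, extent = ext)
}

#' Write an age-group rates table
#'
#' @param rates an \linkS4class{AgeGroupRates} object.
#' @param path file path.
#' @param label stratum label stored in the first column.
#' @export
writeRatesCsv <- function(rates, path, label = "all") {
  df <- data.frame(stratum = label, group = AGE_GROUP_LABELS,
                   births = rates@births, exposure = rates@exposure,
                   asfr = rates@asfr, tfr = rates@tfr,
                   complete = rates@complete,
                   dropped_births = rates@droppedBirths)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

configToList <- function(config) {
  list(extent = as.list(config@extent), cell_km = config@cellKm,
       n_clusters = config@nClusters, urban_fraction = config@urbanFraction,
       women_per_cluster = config@womenPerCluster,
       true_beta = as.list(config@trueBeta),
       true_intercept = config@trueIntercept,
       matern = list(sigma2 = config@matern@sigma2,
                     range_km = config@matern@rangeKm, nu = config@matern@nu),
       base_asfr = config@baseAsfr, n_cities = config@nCities,
       n_facilities = config@nFacilities, survey_year = config@surveyYear,
       seed = config@seed)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Sequences every stage on one seeded synthetic world: simulate (clusters,
#' birth histories, covariate rasters, religion surface, admin units) ->
#' direct rates -> covariate design matrix with kriged proportion-Muslim
#' layer -> geostatistical fits (spatial and non-spatial, TFR and summed
#' ASFR) -> pixel prediction -> admin aggregation -> range report. All
#' artifacts are written under \code{outDir} as plain-text formats (CSV,
#' ASCII grid, GeoJSON, YAML) together with an MD5 manifest, and the key
#' objects are returned invisibly.
#'
#' @param config a \linkS4class{SimulationConfig}; its seed drives every
#'   stage through named substreams.
#' @param outDir output directory (created if missing).
#' @param windowMonths exposure window for the direct rates.
#' @param predictGridKm resolution of the prediction grid (default: the
#'   simulation grid coarsened to 2 km to keep the run light).
#' @return invisibly, a list with the main stage outputs.
#' @export
runAll <- function(config, outDir, windowMonths = 36L, predictGridKm = 2) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outDir, ...)
  yaml::write_yaml(configToList(config), pth("config.yaml"))

  # --- simulate ---------------------------------------------------------
  stack <- simulateCovariateRasters(config)
  grid <- gridSpec(stack)
  field <- simulateMaternField(grid, config@matern,
                               substreamSeed(config@seed, "field"))
  religion <- simulateReligionSurface(config)
  genStack <- covariateStack(c(stack@layers, list(prop_muslim = religion)))
  clusters <- simulateClusters(config)
  props <- simulateClusterProportions(clusters, religion, config)
  women <- simulateBirthHistories(clusters, genStack, field, config,
                                  windowMonths)
  # admin borders snap to the (coarser) prediction grid so every district
  # contains at least one prediction pixel centre
  pGrid <- gridFromExtent(config@extent, predictGridKm)
  admin <- simulateAdminUnits(pGrid, nRegions = 4L, nZonesPerRegion = 2L,
                              nDistrictsPerZone = 2L,
                              seed = substreamSeed(config@seed, "admin"))
  writeClustersCsv(clusters, pth("clusters.csv"))
  writeWomenCsv(women, pth("women.csv"))
  write.csv(props, pth("cluster_proportions.csv"), row.names = FALSE,
            quote = FALSE)
  for (nm in layerNames(stack))
    writeAsciiGrid(getLayer(stack, nm), pth(paste0(nm, ".asc")))
  writeAdminGeoJSON(admin, pth("admin.geojson"))

  # --- direct rates -----------------------------------------------------
  national <- weightedRates(women, windowMonths)
  writeRatesCsv(national, pth("rates_national.csv"))
  byUrban <- ratesBy(women, clusters, "urban", windowMonths)
  trend <- data.frame(year = config@surveyYear, tfr = tfr(national),
                      asfr_sum = tfr(national) / 5,
                      tfr_urban = tfr(byUrban$urban),
                      tfr_rural = tfr(byUrban$rural))
  write.csv(trend, pth("national_trend.csv"), row.names = FALSE,
            quote = FALSE)
  clusterRates <- ratesBy(women, clusters, "cluster", windowMonths)
  yTfr <- vapply(clusterRates[clusters$cluster_id], tfr, numeric(1))

  # --- covariates + kriging --------------------------------------------
  kfit <- krigeFit(props$x_km, props$y_km, props$proportion,
                   nWeights = props$n_women)
  ksurf <- krigePredict(kfit, grid)
  ksurf$mean@name <- "prop_muslim"
  writeAsciiGrid(ksurf$mean, pth("prop_muslim_mean.asc"))
  writeAsciiGrid(ksurf$sd, pth("prop_muslim_sd.asc"))
  analysisStack <- covariateStack(c(stack@layers,
                                    list(prop_muslim = ksurf$mean)))
  design <- buildDesignMatrix(clusters, analysisStack)
  cc <- collinearityCheck(design)
  write.csv(as.data.frame(cc$correlation), pth("collinearity.csv"),
            row.names = TRUE, quote = FALSE)
  write.csv(as.data.frame(design@X), pth("design.csv"), row.names = FALSE,
            quote = FALSE)
  yaml::write_yaml(list(center = as.list(design@center),
                        scale = as.list(design@scale)),
                   pth("standardization.yaml"))

  # --- geostatistical fits ---------------------------------------------
  locations <- cbind(clusters$x_km, clusters$y_km)
  fits <- list(
    tfr_spatial = fitGeostat(yTfr, design, locations, spatial = TRUE),
    tfr_nonspatial = fitGeostat(yTfr, design, spatial = FALSE),
    asfr_spatial = fitGeostat(yTfr / 5, design, locations, spatial = TRUE),
    asfr_nonspatial = fitGeostat(yTfr / 5, design, spatial = FALSE))
  coefTable <- do.call(rbind, lapply(names(fits), function(nm) {
    st <- posteriorSummary(fits[[nm]])
    cbind(model = nm, st)
  }))
  write.csv(coefTable, pth("coefficients.csv"), row.names = FALSE,
            quote = FALSE)
  cmp <- compareModels(fits$tfr_spatial, fits$tfr_nonspatial)
  write.csv(data.frame(response = "tfr", delta_log_evidence = cmp$delta,
                       preferred = cmp$preferred),
            pth("model_comparison.csv"), row.names = FALSE, quote = FALSE)

  # --- prediction + aggregation ----------------------------------------
  pStack <- covariateStack(setNames(lapply(layerNames(analysisStack),
    function(nm) resampleToGrid(getLayer(analysisStack, nm), pGrid)),
    layerNames(analysisStack)))
  surface <- predictPixels(fits$tfr_spatial, pStack, design,
                           weightCutoff = 0.99)
  writeAsciiGrid(rasterLayer(surface@mean, pGrid, "tfr_mean"),
                 pth("tfr_mean.asc"))
  writeAsciiGrid(rasterLayer(surface@sd, pGrid, "tfr_sd"), pth("tfr_sd.asc"))
  writeAsciiGrid(rasterLayer(surface@lower95, pGrid, "tfr_lower95"),
                 pth("tfr_lower95.asc"))
  writeAsciiGrid(rasterLayer(surface@upper95, pGrid, "tfr_upper95"),
                 pth("tfr_upper95.asc"))
  pop <- resampleToGrid(getLayer(stack, "pop_density"), pGrid)
  estimates <- aggregateSurface(surface, admin, pop)
  write.csv(estimates, pth("estimates.csv"), row.names = FALSE, quote = FALSE)
  ranges <- rangeReport(estimates)
  write.csv(ranges, pth("range_report.csv"), row.names = FALSE, quote = FALSE)

  # --- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(outDir), "manifest.csv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outDir, files))),
                         stringsAsFactors = FALSE)
  write.csv(manifest, pth("manifest.csv"), row.names = FALSE, quote = FALSE)

  invisible(list(stack = stack, field = field, clusters = clusters,
                 women = women, admin = admin, national = national,
                 clusterTfr = yTfr, krige = kfit, design = design,
                 collinearity = cc, fits = fits, comparison = cmp,
                 surface = surface, estimates = estimates, ranges = ranges,
                 manifest = manifest))
}
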