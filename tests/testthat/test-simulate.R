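test_that("covariate rasters cover the grid and vanish at seeded points", {
  cfg <- tinyConfig(seed = 5)
  st <- simulateCovariateRasters(cfg)
  g <- gridSpec(st)
  expect_equal(c(g@nRows, g@nCols), c(60L, 60L))
  for (nm in layerNames(st))
    expect_false(anyNA(rasterValues(getLayer(st, nm))))
  # city points are snapped to pixel centres: exact zero at the city pixel
  expect_equal(min(rasterValues(getLayer(st, "travel_time_city"))), 0)
  expect_equal(min(rasterValues(getLayer(st, "dist_health_facility"))), 0)
  expect_true(all(rasterValues(getLayer(st, "pop_density")) > 0))
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- tinyConfig(seed = 9)
  a <- simWorld(cfg)
  b <- simWorld(cfg)
  expect_identical(rasterValues(getLayer(a$stack, "altitude")),
                   rasterValues(getLayer(b$stack, "altitude")))
  expect_identical(rasterValues(a$field), rasterValues(b$field))
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$women, b$women)
})

test_that("cluster simulation honours strata counts and weight scaling", {
  cfg0 <- tinyConfig(seed = 2, urbanFraction = 0)
  expect_true(all(simulateClusters(cfg0)$urban == 0))
  cfg <- simulationConfig(seed = 2, nClusters = 250, urbanFraction = 0.2)
  cl <- simulateClusters(cfg)
  expect_equal(sum(cl$urban), 50)
  expect_lt(abs(mean(cl$weight) - 1), 1e-12)
  e <- cfg@extent
  expect_true(all(cl$x_km >= e["xmin"] & cl$x_km <= e["xmax"] &
                  cl$y_km >= e["ymin"] & cl$y_km <= e["ymax"]))
  expect_error(simulateClusters(tinyConfig(nClusters = 1e6)), "exceeds")
})

test_that("degenerate configurations are rejected", {
  expect_error(simulationConfig(extent = c(xmin = 0, xmax = 0, ymin = 0,
                                           ymax = 10)), "degenerate")
  expect_error(simulationConfig(urbanFraction = 1.5), "urbanFraction")
  expect_error(simulationConfig(baseAsfr = rep(-1, 7)), "baseAsfr")
})

test_that("a zero-variance Matern field is identically zero", {
  g <- gridFromExtent(c(xmin = 0, xmax = 20, ymin = 0, ymax = 20), 1)
  f <- simulateMaternField(g, maternParams(0, 10, 1), 3)
  expect_true(all(rasterValues(f) == 0))
})

test_that("Matern field draws match their moments over repeated draws", {
  # Monte-Carlo oracle: 200 draws on a grid fine enough that no coarsening
  # happens; pixel variance ~ sigma2 and the lag-range correlation ~ the
  # closed-form Matern value.
  g <- gridFromExtent(c(xmin = 0, xmax = 25, ymin = 0, ymax = 25), 1)
  pars <- maternParams(sigma2 = 2, rangeKm = 10, nu = 1)
  draws <- vapply(1:200, function(s) {
    v <- rasterValues(simulateMaternField(g, pars, s))
    c(v[13, 5], v[13, 15])   # two pixels 10 km apart (the range)
  }, numeric(2))
  expect_lt(abs(var(draws[1, ]) - pars@sigma2) / pars@sigma2, 0.15)
  expect_lt(abs(cor(draws[1, ], draws[2, ]) -
                maternCorrelation(10, 10, 1)), 0.1)
})

test_that("birth histories respect the window and scale with local rates", {
  cfg <- tinyConfig(seed = 21)
  w <- simWorld(cfg)
  kids <- unlist(w$women$child_dobs_cmc)
  mi <- rep(seq_len(nrow(w$women)), lengths(w$women$child_dobs_cmc))
  doi <- w$women$doi_cmc[mi]
  expect_true(all(kids > doi - 36 & kids <= doi))
  expect_error(
    simulateBirthHistories(w$clusters, w$stack, w$field, cfg),
    "prop_muslim")   # missing covariate layer is named
})

test_that("null-effect simulation recovers the base TFR through the rates module", {
  # round-trip oracle: no covariate effects, no field, intercept = base TFR
  cfg <- simulationConfig(seed = 31, nClusters = 200, womenPerCluster = 25,
                          trueBeta = c(travel_time_city = 0),
                          trueIntercept = 4.5,
                          matern = maternParams(0, 30, 1))
  st <- simulateCovariateRasters(cfg)
  f <- simulateMaternField(gridSpec(st), maternParams(0, 30, 1), 1)
  cl <- simulateClusters(cfg)
  women <- simulateBirthHistories(cl, st, f, cfg)
  est <- tfr(weightedRates(women))
  expect_lt(abs(est - 4.5) / 4.5, 0.05)
})

test_that("admin units partition the extent and nest exactly", {
  g <- gridFromExtent(c(xmin = 0, xmax = 40, ymin = 0, ymax = 40), 1)
  one <- simulateAdminUnits(g, 1L, 1L, 1L, seed = 4)
  r1 <- one@units[one@units$level == "region", ]
  expect_equal(unname(unlist(r1[, c("xmin", "xmax", "ymin", "ymax")])),
               c(0, 40, 0, 40))
  adm <- simulateAdminUnits(g, 3L, 2L, 2L, seed = 4)
  u <- adm@units
  area <- function(d) sum((d$xmax - d$xmin) * (d$ymax - d$ymin))
  for (rid in u$id[u$level == "region"]) {
    reg <- u[u$id == rid, ]
    zones <- u[u$level == "zone" & u$parent_id == rid, ]
    expect_equal(area(zones), area(reg), tolerance = 1e-9)
    for (zid in zones$id) {
      z <- u[u$id == zid, ]
      dists <- u[u$level == "district" & u$parent_id == zid, ]
      expect_equal(area(dists), area(z), tolerance = 1e-9)
      # nesting: each district inside its zone, each zone inside its region
      expect_true(all(dists$xmin >= z$xmin - 1e-12 &
                      dists$xmax <= z$xmax + 1e-12 &
                      dists$ymin >= z$ymin - 1e-12 &
                      dists$ymax <= z$ymax + 1e-12))
      expect_true(z$xmin >= reg$xmin && z$xmax <= reg$xmax)
    }
  }
  expect_error(simulateAdminUnits(g, 100L, 1L, 1L, seed = 1), "finer")
})
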