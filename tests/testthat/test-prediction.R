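constStack <- function(grid, names, values) {
  covariateStack(setNames(lapply(seq_along(names), function(i)
    rasterLayer(matrix(values[i], grid@nRows, grid@nCols), grid, names[i])),
    names))
}

# A fitted toy model with two covariates on a 20 x 20 world.
toyFit <- function(seed = 61, n = 18, single_node = TRUE) {
  set.seed(seed)
  loc <- cbind(runif(n, 2, 18), runif(n, 2, 18))
  Xr <- cbind(a = rnorm(n, 5, 2), b = rnorm(n, -1, 0.5))
  ctr <- colMeans(Xr); scl <- apply(Xr, 2, sd)
  Xs <- sweep(sweep(Xr, 2, ctr), 2, scl, "/")
  design <- new("DesignMatrix", X = Xs, center = ctr, scale = scl)
  y <- as.vector(3 + 0.5 * Xs[, 1] + rnorm(n, 0, 0.3))
  hg <- if (single_node) list(sigma2 = 0.4, rangeKm = 5, nugget = 0.1)
        else list(sigma2 = c(0.2, 0.6), rangeKm = c(3, 8), nugget = 0.1)
  fit <- fitGeostat(y, design, loc, spatial = TRUE, hyperGrid = hg,
                    checkCollinearity = FALSE)
  list(fit = fit, design = design, loc = loc, y = y, hg = hg, Xs = Xs)
}

test_that("far-field pixels with mean covariates revert to the intercept", {
  tf <- toyFit()
  far <- makeGrid(500, 502, 1, 2L, 2L)
  stack <- constStack(far, c("a", "b"), c(tf$design@center))
  surf <- predictPixels(tf$fit, stack, tf$design)
  st <- posteriorSummary(tf$fit)
  b0 <- st$mean[st$term == "intercept"]
  expect_true(all(abs(surf@mean - b0) < 3 * st$sd[st$term == "intercept"]))
  # far from data the field is unconstrained: sd ~ sqrt(sigma2 + var(b0))
  expect_true(all(surf@sd > sqrt(tf$hg$sigma2) * 0.9))
})

test_that("pixel posterior matches the dense joint-Gaussian oracle", {
  tf <- toyFit()
  g <- makeGrid(0, 20, 1, 20L, 20L)
  # rasters that reproduce standardized values z = (v - center)/scale
  set.seed(7)
  va <- matrix(rnorm(400, 5, 2), 20, 20)
  vb <- matrix(rnorm(400, -1, 0.5), 20, 20)
  stack <- covariateStack(list(a = rasterLayer(va, g, "a"),
                               b = rasterLayer(vb, g, "b")))
  surf <- predictPixels(tf$fit, stack, tf$design, weightCutoff = 1)
  # oracle: exact conditional of (latent pixel value) given y in the joint
  # Gaussian over (y, beta, u_pixels), brute-force with solve()
  n <- length(tf$y); s2 <- tf$hg$sigma2; phi <- tf$hg$rangeKm
  tau <- tf$hg$nugget; sb <- tf$fit@priorSdBeta
  Z <- cbind(1, tf$Xs)
  pc <- pixelCenters(g)
  Zp <- cbind(1, (as.vector(va) - tf$design@center["a"]) / tf$design@scale["a"],
              (as.vector(vb) - tf$design@center["b"]) / tf$design@scale["b"])
  R <- s2 * matrix(maternCorrelation(as.vector(as.matrix(dist(tf$loc))),
                                     phi, 1), n)
  V <- sb^2 * tcrossprod(Z) + R + diag(tau, n)
  Dc <- sqrt(outer(pc[, "x"], tf$loc[, 1], "-")^2 +
             outer(pc[, "y"], tf$loc[, 2], "-")^2)
  Kp <- s2 * matrix(maternCorrelation(as.vector(Dc), phi, 1), nrow(pc))
  # Cov(latent_p, y) = Zp B Z' + Kp ; Var(latent_p) = Zp B Zp' + s2
  CovPy <- sb^2 * Zp %*% t(Z) + Kp
  Vi <- solve(V)
  oMean <- as.vector(CovPy %*% Vi %*% tf$y)
  oVar <- sb^2 * rowSums(Zp^2) + s2 - rowSums((CovPy %*% Vi) * CovPy)
  expect_equal(as.vector(surf@mean), pmax(oMean, 0), tolerance = 1e-6)
  expect_equal(as.vector(surf@sd), sqrt(pmax(oVar, 0)), tolerance = 1e-6)
})

test_that("prediction sd is smallest at the data and grows along a ray", {
  set.seed(71)
  n <- 12
  loc <- cbind(rep(2, n) + runif(n, 0, 0.5), rep(2, n) + runif(n, 0, 0.5))
  Xs <- cbind(a = scale(rnorm(n))[, 1])
  design <- new("DesignMatrix", X = Xs, center = c(a = 0), scale = c(a = 1))
  y <- 3 + rnorm(n, 0, 0.2)
  fit <- fitGeostat(y, design, loc, spatial = TRUE,
                    hyperGrid = list(sigma2 = 0.5, rangeKm = 6,
                                     nugget = 0.05),
                    checkCollinearity = FALSE)
  g <- makeGrid(0, 4, 2, 1L, 15L)    # one row of pixels marching east
  stack <- constStack(g, "a", 0)
  surf <- predictPixels(fit, stack, design)
  sds <- as.vector(surf@sd)
  expect_true(all(diff(sds[2:15]) > -1e-9))
  expect_lt(sds[2], sds[15])
})

test_that("aggregation is a population-weighted convex combination", {
  g <- makeGrid(0, 4, 1, 4L, 4L)
  adm <- simulateAdminUnits(g, 2L, 2L, 1L, seed = 3)
  mk <- function(v) matrix(v, 4, 4)
  surf <- new("PredictionSurface", grid = g, mean = mk(2.5), sd = mk(0.1),
              lower95 = mk(2.0), upper95 = mk(3.0))
  pop <- rasterLayer(matrix(runif(16, 1, 5), 4, 4), g, "pop")
  agg <- aggregateSurface(surf, adm, pop)
  expect_true(all(abs(agg$estimate - 2.5) < 1e-12))
  expect_true(all(abs(agg$lower - 2.0) < 1e-12))
  # non-constant surface: estimates stay inside the pixel range and levels
  # stay mutually consistent
  vals <- matrix(seq(1, 7, length.out = 16), 4, 4)
  surf2 <- new("PredictionSurface", grid = g, mean = vals, sd = mk(0.1),
               lower95 = vals - 1, upper95 = vals + 1)
  agg2 <- aggregateSurface(surf2, adm, pop)
  expect_true(all(agg2$estimate >= min(vals) & agg2$estimate <= max(vals)))
  pv <- as.vector(rasterValues(pop))
  regions <- agg2[agg2$level == "region", ]
  nat <- agg2$estimate[agg2$level == "national"]
  expect_equal(nat, sum(regions$estimate * regions$population) /
                 sum(regions$population), tolerance = 1e-9)
  # zones reaggregate to their region
  for (rid in regions$unit_id) {
    zs <- agg2[agg2$level == "zone" & agg2$parent_id == rid, ]
    expect_equal(sum(zs$estimate * zs$population) / sum(zs$population),
                 regions$estimate[regions$unit_id == rid], tolerance = 1e-9)
  }
  # area weighting equals population weighting under constant population
  popc <- rasterLayer(matrix(2, 4, 4), g, "pop")
  expect_equal(aggregateSurface(surf2, adm, popc)$estimate,
               aggregateSurface(surf2, adm, popc, weighting = "area")$estimate,
               tolerance = 1e-12)
  # zero-population unit: flagged, unweighted mean (known geometry)
  admz <- new("AdminUnits", units = data.frame(
    id = c("R1", "R2"), level = "region", parent_id = "national",
    xmin = c(0, 2), xmax = c(2, 4), ymin = 0, ymax = 4,
    stringsAsFactors = FALSE),
    extent = c(xmin = 0, xmax = 4, ymin = 0, ymax = 4))
  pz <- rasterValues(pop); pz[, 1:2] <- 0
  aggz <- aggregateSurface(surf2, admz, rasterLayer(pz, g, "pop"))
  left <- aggz[aggz$level == "region" & aggz$unit_id == "R1", ]
  expect_true(left$flag_zero_pop)
  expect_equal(left$estimate, mean(vals[, 1:2]), tolerance = 1e-12)
  smallAdm <- simulateAdminUnits(makeGrid(0, 2, 1, 2L, 2L), 1L, 1L, 1L, 2)
  expect_error(aggregateSurface(surf2, smallAdm,
                                rasterLayer(matrix(1, 2, 2),
                                            makeGrid(0, 2, 1, 2L, 2L))),
               "not on the surface grid")
})

test_that("range reports nest across administrative levels", {
  g <- makeGrid(0, 8, 1, 8L, 8L)
  adm <- simulateAdminUnits(g, 2L, 2L, 2L, seed = 5)
  set.seed(5)
  vals <- matrix(runif(64, 1, 7), 8, 8)
  surf <- new("PredictionSurface", grid = g, mean = vals,
              sd = matrix(0.1, 8, 8), lower95 = vals - 1,
              upper95 = vals + 1)
  pop <- rasterLayer(matrix(runif(64, 0.5, 2), 8, 8), g, "pop")
  agg <- aggregateSurface(surf, adm, pop)
  rr <- rangeReport(agg)
  spread <- function(lv) {
    d <- rr[rr$level == lv, ]
    c(d$min, d$max)
  }
  dd <- spread("district"); zz <- spread("zone"); reg <- spread("region")
  # averaging contracts ranges: district range contains zone range, etc.
  expect_lte(dd[1], zz[1]); expect_gte(dd[2], zz[2])
  expect_lte(zz[1], reg[1]); expect_gte(zz[2], reg[2])
  one <- rangeReport(agg[agg$level == "national", ])
  expect_equal(one$min, one$max)
  # deterministic regeneration
  agg2 <- aggregateSurface(surf, adm, pop)
  expect_identical(rangeReport(agg2), rr)
})
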