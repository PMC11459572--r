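test_that("spline basis partitions unity and penalizes curvature only", {
  set.seed(6)
  x <- rnorm(100)
  sb <- splineBasis(x, 8)
  expect_true(all(abs(rowSums(sb$B) - 1) < 1e-12))
  # second differences annihilate linear coefficient sequences
  cl <- 2 + 3 * seq_len(8)
  expect_lt(as.numeric(t(cl) %*% sb$P %*% cl), 1e-18)
  expect_identical(sb$B, splineBasis(x, 8)$B)
  expect_error(splineBasis(rep(1:3, 10), 8), "distinct")
  expect_error(splineBasis(x, 3), ">= 4")
})

test_that("marginal log-likelihood matches the standard normal and dense oracle", {
  # single observation, total variance 1, y = 0: standard normal density
  expect_equal(marginalLoglik(0, nugget = 0.6, sigma2 = 0.4,
                              locations = cbind(0, 0)),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  set.seed(14)
  n <- 10
  X <- cbind(1, rnorm(n), rnorm(n))
  loc <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  y <- rnorm(n)
  for (pars in list(c(0.5, 3, 0.2), c(2, 8, 1))) {
    V <- pars[1] * matrix(maternCorrelation(as.vector(as.matrix(dist(loc))),
                                            pars[2], 1), n) +
      diag(pars[3], n) + 100 * tcrossprod(X)
    expect_equal(marginalLoglik(y, X, loc, sigma2 = pars[1],
                                rangeKm = pars[2], nugget = pars[3],
                                priorSdBeta = 10),
                 denseMvnLogLik(y, V), tolerance = 1e-8)
  }
})

test_that("flat-prior non-spatial fit reproduces least squares", {
  set.seed(21)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- 1.5 + X %*% c(0.4, -0.3, 0.1) + rnorm(n, 0, 0.5)
  fit <- fitGeostat(as.vector(y), X, spatial = FALSE, priorSdBeta = 1e3,
                    hyperGrid = list(sigma2 = 0, rangeKm = 1, nugget = 0.25))
  ls <- coef(lm(y ~ X))
  expect_equal(posteriorSummary(fit)$mean, unname(ls), tolerance = 1e-6)
})

test_that("per-node posterior equals the dense conditional-Gaussian oracle", {
  set.seed(33)
  n <- 25
  X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n))
  loc <- cbind(runif(n, 0, 15), runif(n, 0, 15))
  y <- as.vector(2 + X[, 2] * 0.5 + rnorm(n, 0, 0.4))
  s2 <- 0.3; phi <- 5; tau <- 0.2; sb <- 10
  fit <- fitGeostat(y, X[, -1], loc, spatial = TRUE, priorSdBeta = sb,
                    hyperGrid = list(sigma2 = s2, rangeKm = phi,
                                     nugget = tau),
                    checkCollinearity = FALSE)
  # oracle: posterior precision of beta is X' C^-1 X + I/sb^2
  C <- s2 * matrix(maternCorrelation(as.vector(as.matrix(dist(loc))),
                                     phi, 1), n) + diag(tau, n)
  Ci <- solve(C)
  prec <- t(X) %*% Ci %*% X + diag(1 / sb^2, 3)
  pcov <- solve(prec)
  pmean <- as.vector(pcov %*% t(X) %*% Ci %*% y)
  st <- posteriorSummary(fit)
  expect_equal(st$mean, pmean, tolerance = 1e-8)
  expect_equal(st$sd, unname(sqrt(diag(pcov))), tolerance = 1e-8)
  # single Gaussian node: the 95% interval is the normal one
  expect_equal(st$upper95,
               unname(pmean + qnorm(0.975) * sqrt(diag(pcov))),
               tolerance = 1e-4)
  expect_true(all(st$lower95 <= st$mean & st$mean <= st$upper95))
})

test_that("finite priors shrink the coefficient norm", {
  set.seed(40)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.vector(2 + X %*% c(1, -1, 0.5) + rnorm(n, 0, 1))
  hg <- list(sigma2 = 0, rangeKm = 1, nugget = 1)
  tight <- fitGeostat(y, X, spatial = FALSE, priorSdBeta = 0.5,
                      hyperGrid = hg)
  flat <- fitGeostat(y, X, spatial = FALSE, priorSdBeta = 1e5,
                     hyperGrid = hg)
  expect_lt(sqrt(sum(posteriorSummary(tight)$mean^2)),
            sqrt(sum(posteriorSummary(flat)$mean^2)))
})

test_that("fits are reproducible and node weights normalize", {
  cfg <- tinyConfig(seed = 10)
  w <- simWorld(cfg)
  y <- clusterTfr(w$women, w$clusters)
  d <- buildDesignMatrix(w$clusters, w$genStack)
  loc <- cbind(w$clusters$x_km, w$clusters$y_km)
  f1 <- fitGeostat(y, d, loc, spatial = TRUE)
  f2 <- fitGeostat(y, d, loc, spatial = TRUE)
  expect_identical(posteriorSummary(f1), posteriorSummary(f2))
  expect_lt(abs(sum(f1@nodes$weight) - 1), 1e-12)
  expect_error(fitGeostat(y[1:5], d@X[1:5, ], loc[1:5, ], spatial = TRUE),
               "at least 10")
})

test_that("model comparison is zero for identical fits and checks sizes", {
  set.seed(2)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.vector(X %*% c(1, -1) + rnorm(40))
  f <- fitGeostat(y, X, spatial = FALSE)
  cmp <- compareModels(f, f)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$preferred, "tie")
  f2 <- fitGeostat(y[1:20], X[1:20, ], spatial = FALSE)
  expect_error(compareModels(f, f2), "different numbers")
})

test_that("smooth terms capture a nonlinear effect", {
  set.seed(50)
  n <- 120
  x <- sort(runif(n, -2, 2))
  X <- cbind(s = x, lin = rnorm(n))
  y <- sin(1.5 * x) + 0.3 * X[, "lin"] + rnorm(n, 0, 0.2)
  fit <- fitGeostat(y, X, spatial = FALSE, smoothTerms = "s",
                    hyperGrid = list(sigma2 = 0, rangeKm = 1,
                                     nugget = c(0.04, 0.1)),
                    checkCollinearity = FALSE)
  # the linear coefficient survives; the model outperforms a linear-only fit
  lin <- fitGeostat(y, X, spatial = FALSE,
                    hyperGrid = list(sigma2 = 0, rangeKm = 1,
                                     nugget = c(0.04, 0.1)),
                    checkCollinearity = FALSE)
  expect_gt(fit@logML, lin@logML)
  st <- posteriorSummary(fit)
  expect_lt(abs(st$mean[st$term == "lin"] - 0.3), 0.15)
})
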