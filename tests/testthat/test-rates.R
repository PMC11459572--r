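test_that("exposure splits the window exactly across age groups", {
  doi <- 1400
  # exactly 20 years at the window start: all 36 months in [20,25)
  expect_equal(exposureByAgeGroup(doi - 35 - 240, doi),
               c(0, 3, 0, 0, 0, 0, 0))
  # 24y0m at the window start: 12 months in [20,25), 24 in [25,30)
  expect_equal(exposureByAgeGroup(doi - 35 - 288, doi),
               c(0, 1, 2, 0, 0, 0, 0))
  # aged 14.5 at the window start, turns 15 after 6 months: 30 months in 15-19
  expect_equal(exposureByAgeGroup(doi - 35 - 174, doi),
               c(30 / 12, 0, 0, 0, 0, 0, 0))
  expect_error(exposureByAgeGroup(1000, 1400, windowMonths = 0), "positive")
})

test_that("exposure conserves the window against the month-loop oracle", {
  set.seed(77)
  for (i in 1:200) {
    doi <- sample(1200:1500, 1)
    dob <- doi - sample(150:640, 1)
    e <- exposureByAgeGroup(dob, doi)
    o <- oracleExposure(dob, doi)
    expect_identical(e, o$years)
    expect_equal(sum(e) + o$outOfRange, 3)   # exact: integer month arithmetic
  }
})

test_that("births land in the mother's age group at delivery", {
  expect_equal(unclass(birthsByAgeGroup(1000, 1400, integer()))[1:7],
               rep(0, 7), ignore_attr = TRUE)
  b <- birthsByAgeGroup(1128, 1400, 1380)   # mother 21 years old at birth
  expect_equal(b[2], 1)
  expect_equal(sum(b), 1)
  # right-closed window: a birth in the interview month is included
  b2 <- birthsByAgeGroup(1000, 1400, 1400)
  expect_equal(sum(b2), 1)
  # a birth one month past the 36-month window is not
  b3 <- birthsByAgeGroup(1000, 1400, 1400 - 36)
  expect_equal(sum(b3), 0)
  expect_error(birthsByAgeGroup(1000, 1400, 1450), "after the interview")
  # under-15 delivery: dropped from the counts, kept in the diagnostic tally
  b4 <- birthsByAgeGroup(1230, 1400, 1400)   # mother 170 months old
  expect_equal(sum(b4), 0)
  expect_equal(attr(b4, "dropped"), 1)
})

test_that("weighted rates reduce correctly in edge cases", {
  w2 <- data.frame(woman_id = c("a", "b"), cluster_id = "c1",
                   dob_cmc = c(1400 - 35 - 240, 1400 - 35 - 240),
                   doi_cmc = 1400, weight = c(2, 0))
  w2$child_dobs_cmc <- list(c(1380, 1390), c(1380))
  r <- weightedRates(w2)
  # zero-weight woman contributes nothing; equal scale cancels in the ratio
  expect_equal(asfr(r)[["20-24"]], 2 / 3)
  # two women with 3 woman-years each in [20,25) and 3 births total
  w3 <- w2; w3$weight <- c(1, 1)
  r3 <- weightedRates(w3)
  expect_equal(asfr(r3)[["20-24"]], 3 / 6)
  expect_equal(tfr(r3), 5 * sum(asfr(r3)))
  # all-equal weights match the unweighted estimator
  w4 <- w3; w4$weight <- c(7, 7)
  expect_equal(asfr(weightedRates(w4)), asfr(r3))
  wneg <- w3; wneg$weight <- c(1, -1)
  expect_error(weightedRates(wneg), "negative")
  old <- data.frame(woman_id = "z", cluster_id = "c", dob_cmc = 100,
                    doi_cmc = 800, weight = 1)   # aged 58: no exposure
  old$child_dobs_cmc <- list(integer())
  expect_error(weightedRates(old), "exposure")
})

test_that("vectorized aggregation equals the per-woman operations", {
  cfg <- tinyConfig(seed = 13)
  w <- simWorld(cfg)$women
  r <- weightedRates(w)
  births <- numeric(7); exposure <- numeric(7)
  for (i in seq_len(nrow(w))) {
    births <- births + w$weight[i] *
      birthsByAgeGroup(w$dob_cmc[i], w$doi_cmc[i], w$child_dobs_cmc[[i]])
    exposure <- exposure + w$weight[i] *
      exposureByAgeGroup(w$dob_cmc[i], w$doi_cmc[i])
  }
  expect_equal(r@births, c(births), tolerance = 1e-12)
  expect_equal(r@exposure, c(exposure), tolerance = 1e-12)
  expect_equal(tfr(r), 5 * sum(asfr(r)), tolerance = 1e-12)
})

test_that("TFR is five times the summed schedule", {
  expect_equal(tfrFromAsfr(rep(0.2, 7)), 7)
  expect_equal(tfrFromAsfr(rep(0, 7)), 0)
  expect_error(tfrFromAsfr(c(rep(0.1, 6), -0.1)), "nonnegative")
  expect_error(tfrFromAsfr(rep(0.1, 5)), "7 age-specific")
})

test_that("rates by stratum split the sample as labelled", {
  cfg <- tinyConfig(seed = 19, urbanFraction = 0.3)
  w <- simWorld(cfg)
  byU <- ratesBy(w$women, w$clusters, "urban")
  expect_setequal(names(byU), c("urban", "rural"))
  all <- weightedRates(w$women)
  # weighted births partition across the strata
  expect_equal(byU$urban@births + byU$rural@births, all@births,
               tolerance = 1e-9)
  byC <- ratesBy(w$women, w$clusters, "cluster")
  expect_equal(length(byC), nrow(w$clusters))
})
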