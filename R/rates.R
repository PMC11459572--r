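# Direct estimation of ASFR/TFR from birth histories.
#
# All date arithmetic is in whole months (CMC convention: day of month is
# unknown). The exposure window is the right-closed interval of
# windowMonths months ending at the interview month, i.e. months
# (doi - windowMonths, doi]. Age at calendar month m is m - dob_cmc; the
# seven 5-year groups cover ages [180, 420) months with lower-inclusive
# boundaries at exact multiples of 60 months.

AGE_GROUP_LABELS <- c("15-19", "20-24", "25-29", "30-34", "35-39",
                      "40-44", "45-49")

checkWoman <- function(dob_cmc, doi_cmc, child_dobs) {
  if (doi_cmc <= dob_cmc) stop("interview date must be after birth date")
  if (length(child_dobs) && any(child_dobs > doi_cmc))
    stop("child birth date after the interview date")
}

#' Woman-years of exposure by 5-year age group
#'
#' Splits a woman's time in the window (the \code{windowMonths} months up to
#' and including her interview month) across the seven age groups 15-49 by
#' exact integer month arithmetic. Months lived outside ages [15, 50)
#' contribute no exposure.
#'
#' @param dob_cmc,doi_cmc birth and interview months (months-since-epoch).
#' @param windowMonths window length, default 36.
#' @return numeric(7), woman-years (months / 12) per age group.
#' @examples
#' # woman exactly 20 years old at the window start: all 36 months in 20-24
#' doi <- 1400
#' exposureByAgeGroup(dob_cmc = doi - 35 - 240, doi_cmc = doi)
#' @export
exposureByAgeGroup <- function(dob_cmc, doi_cmc, windowMonths = 36L) {
  if (windowMonths <= 0) stop("windowMonths must be positive")
  checkWoman(dob_cmc, doi_cmc, integer())
  a0 <- (doi_cmc - windowMonths + 1) - dob_cmc   # age at first window month
  a1 <- doi_cmc - dob_cmc                        # age at interview month
  months <- numeric(7)
  for (g in 1:7) {
    glo <- 180 + 60 * (g - 1)
    months[g] <- max(0, min(a1, glo + 59) - max(a0, glo) + 1)
  }
  months / 12
}

#' Births by the mother's 5-year age group
#'
#' Counts each child born in the window (right-closed at the interview
#' month) in the mother's age group at the birth month. Births to mothers
#' aged below 15 or 50 and over at delivery are excluded from the counts and
#' returned in the \code{dropped} attribute as a diagnostic tally.
#'
#' @param dob_cmc,doi_cmc mother's birth and interview months.
#' @param child_dobs_cmc vector of the children's birth months.
#' @param windowMonths window length, default 36.
#' @return numeric(7) counts with attribute \code{dropped}.
#' @export
birthsByAgeGroup <- function(dob_cmc, doi_cmc, child_dobs_cmc,
                             windowMonths = 36L) {
  if (windowMonths <= 0) stop("windowMonths must be positive")
  checkWoman(dob_cmc, doi_cmc, child_dobs_cmc)
  counts <- numeric(7)
  dropped <- 0
  inWindow <- child_dobs_cmc > doi_cmc - windowMonths &
    child_dobs_cmc <= doi_cmc
  for (cd in child_dobs_cmc[inWindow]) {
    age <- cd - dob_cmc
    if (age < 180 || age >= 600) { dropped <- dropped + 1; next }
    g <- (age - 180) %/% 60 + 1
    counts[g] <- counts[g] + 1
  }
  attr(counts, "dropped") <- dropped
  counts
}

#' Weighted direct ASFR and TFR estimates
#'
#' Aggregates weighted births and woman-years of exposure over women and
#' forms the seven age-specific rates and the total fertility rate
#' \code{TFR = 5 * sum(ASFR)}. A group with zero exposure contributes 0 to
#' the TFR and clears the completeness flag.
#'
#' @param women data.frame with columns dob_cmc, doi_cmc, weight and
#'   list-column child_dobs_cmc (as produced by
#'   \code{simulateBirthHistories} or \code{readWomenCsv}).
#' @param windowMonths window length, default 36.
#' @return an \linkS4class{AgeGroupRates} object.
#' @export
weightedRates <- function(women, windowMonths = 36L) {
  if (windowMonths <= 0) stop("windowMonths must be positive")
  if (nrow(women) == 0) stop("no women supplied")
  if (any(women$weight < 0)) stop("negative sampling weight")
  dob <- women$dob_cmc; doi <- women$doi_cmc; w <- women$weight
  if (any(doi <= dob)) stop("interview date must be after birth date")
  # vectorized over women: identical arithmetic to exposureByAgeGroup /
  # birthsByAgeGroup (which stay as the per-woman reference operations)
  a0 <- (doi - windowMonths + 1) - dob
  a1 <- doi - dob
  births <- numeric(7); exposure <- numeric(7)
  for (g in 1:7) {
    glo <- 180 + 60 * (g - 1)
    exposure[g] <- sum(w * pmax(0, pmin(a1, glo + 59) - pmax(a0, glo) + 1)) / 12
  }
  nKids <- lengths(women$child_dobs_cmc)
  ch <- unlist(women$child_dobs_cmc, use.names = FALSE)
  mi <- rep(seq_len(nrow(women)), nKids)
  dropped <- 0
  if (length(ch)) {
    if (any(ch > doi[mi])) stop("child birth date after the interview date")
    inWin <- ch > doi[mi] - windowMonths & ch <= doi[mi]
    age <- (ch - dob[mi])[inWin]
    wc <- w[mi][inWin]
    ok <- age >= 180 & age < 600
    dropped <- sum(wc[!ok])
    g <- (age[ok] - 180) %/% 60 + 1
    if (length(g))
      births <- births + vapply(1:7, function(k) sum(wc[ok][g == k]),
                                numeric(1))
  }
  if (sum(exposure) == 0) stop("total exposure is zero")
  pos <- exposure > 0
  rates <- numeric(7)
  rates[pos] <- births[pos] / exposure[pos]
  new("AgeGroupRates", births = births, exposure = exposure, asfr = rates,
      tfr = tfrFromAsfr(rates), complete = all(pos), droppedBirths = dropped)
}

#' Total fertility rate from an age-specific schedule
#'
#' \code{TFR = 5 * sum(ASFR)}: the births a woman would average over her
#' reproductive life if the current 5-year-group rates held.
#'
#' @param rates numeric(7) of nonnegative age-specific rates (births per
#'   woman-year).
#' @return the TFR.
#' @examples
#' tfrFromAsfr(rep(0.2, 7))   # 7
#' @export
tfrFromAsfr <- function(rates) {
  if (length(rates) != 7) stop("expected 7 age-specific rates")
  if (any(rates < 0)) stop("age-specific rates must be nonnegative")
  5 * sum(rates)
}

#' @describeIn asfr the seven age-specific rates
#' @export
setMethod("asfr", "AgeGroupRates", function(x) setNames(x@asfr, AGE_GROUP_LABELS))

#' Age-specific rates of a fit or estimate
#' @param x an AgeGroupRates object.
#' @name asfr
NULL

#' @describeIn tfr the total fertility rate
#' @export
setMethod("tfr", "AgeGroupRates", function(x) x@tfr)

#' Total fertility rate of an estimate
#' @param x an AgeGroupRates object.
#' @name tfr
NULL

setMethod("show", "AgeGroupRates", function(object) {
  cat("Direct fertility estimate (36-month window unless stated)\n")
  df <- data.frame(group = AGE_GROUP_LABELS,
                   births = round(object@births, 2),
                   exposure = round(object@exposure, 2),
                   asfr = round(object@asfr, 4))
  print(df, row.names = FALSE)
  cat(sprintf("TFR = %.3f%s%s\n", object@tfr,
              if (object@complete) "" else "  [incomplete: zero-exposure group]",
              if (object@droppedBirths > 0)
                sprintf("  [%.1f births outside ages 15-49 dropped]",
                        object@droppedBirths) else ""))
})

#' Direct rates by grouping
#'
#' Convenience wrapper computing weighted rates for all women, per stratum
#' (urban/rural) or per cluster.
#'
#' @param women women data.frame (must carry cluster_id).
#' @param clusters cluster data.frame (cluster_id, urban).
#' @param by "all", "urban" or "cluster".
#' @param windowMonths window length.
#' @return for "all", one \linkS4class{AgeGroupRates}; otherwise a named
#'   list of them.
#' @export
ratesBy <- function(women, clusters, by = c("all", "urban", "cluster"),
                    windowMonths = 36L) {
  by <- match.arg(by)
  if (by == "all") return(weightedRates(women, windowMonths))
  key <- switch(by,
    urban = ifelse(clusters$urban[match(women$cluster_id,
                                        clusters$cluster_id)] == 1,
                   "urban", "rural"),
    cluster = women$cluster_id)
  groups <- split(seq_len(nrow(women)), key)
  lapply(groups, function(ix) weightedRates(women[ix, , drop = FALSE],
                                            windowMonths))
}
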