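#' Matern spatial correlation
#'
#' Correlation between two points a distance \code{d} apart under the Matern
#' family, in the range parameterization common in model-based geostatistics:
#' \deqn{\rho(d) = \frac{2^{1-\nu}}{\Gamma(\nu)} (\kappa d)^\nu K_\nu(\kappa d),
#'   \qquad \kappa = \sqrt{8\nu} / \phi,}
#' so that \code{phi} (\code{rangeKm}) is the distance at which correlation
#' has fallen to roughly 0.1 (about 0.13 at \code{nu = 1}). \code{nu = 0.5}
#' gives the exponential kernel \code{exp(-2 d / phi)}.
#'
#' @param d nonnegative distance(s), km. Vectorized.
#' @param phi range parameter, km, > 0.
#' @param nu smoothness, > 0.
#' @return correlation value(s) in (0, 1]; \code{rho(0) = 1}.
#' @examples
#' maternCorrelation(0, 10, 1)            # 1
#' maternCorrelation(5, 10, 0.5)          # exp(-1)
#' @export
maternCorrelation <- function(d, phi, nu) {
  if (any(d < 0)) stop("distances must be >= 0")
  if (length(phi) != 1 || !is.finite(phi) || phi <= 0)
    stop("phi must be a single positive number")
  if (length(nu) != 1 || !is.finite(nu) || nu <= 0)
    stop("nu must be a single positive number")
  kappa <- sqrt(8 * nu) / phi
  out <- numeric(length(d))
  z <- kappa * d
  pos <- z > 0
  out[!pos] <- 1
  if (any(pos)) {
    zp <- z[pos]
    # log-scale evaluation keeps small-z cases from overflowing besselK
    lv <- (1 - nu) * log(2) - lgamma(nu) + nu * log(zp) +
      log(besselK(zp, nu, expon.scaled = TRUE)) - zp
    out[pos] <- pmin(exp(lv), 1)
  }
  out
}

#' Construct Matern hyperparameters
#'
#' @param sigma2 partial sill (>= 0; 0 gives a degenerate constant field).
#' @param rangeKm range in km (distance at which correlation is about 0.1).
#' @param nu smoothness (default 1, the two-dimensional SPDE default).
#' @param nugget iid variance (default 0).
#' @return a \linkS4class{MaternParams} object.
#' @export
maternParams <- function(sigma2, rangeKm, nu = 1, nugget = 0) {
  new("MaternParams", sigma2 = as.numeric(sigma2),
      rangeKm = as.numeric(rangeKm), nu = as.numeric(nu),
      nugget = as.numeric(nugget))
}

setMethod("show", "MaternParams", function(object) {
  cat(sprintf(
    "MaternParams: sigma2 = %.4g, range = %.4g km, nu = %.3g, nugget = %.4g\n",
    object@sigma2, object@rangeKm, object@nu, object@nugget))
})

# Matern correlation matrix over rows of an n x 2 coordinate matrix.
maternCorrMatrix <- function(coords, phi, nu) {
  D <- as.matrix(stats::dist(coords))
  M <- maternCorrelation(as.vector(D), phi, nu)
  matrix(M, nrow(coords), nrow(coords))
}
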