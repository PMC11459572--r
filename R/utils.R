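# Internal helpers: seed fan-out, grid identity, numerics.

# Deterministic sub-seed for a named stage, so each generator stage is
# individually reproducible from one master seed. FNV-style string hash
# folded into [0, 2^31 - 2].
substreamSeed <- function(seed, name) {
  h <- 5381
  for (ch in utf8ToInt(name)) h <- (h * 33 + ch) %% 2147483647
  s <- (as.numeric(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483646) + 1L
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

gridKey <- function(g) {
  c(g@xOrigin, g@yOrigin, g@cellKm, as.numeric(g@nRows), as.numeric(g@nCols))
}

sameGrid <- function(a, b) isTRUE(all.equal(gridKey(a), gridKey(b),
                                            tolerance = 1e-10))

# log(sum(exp(x))) without overflow
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Cholesky with escalating diagonal jitter; errors naming the jitter tried.
cholJitter <- function(S, start = 1e-8, max_jitter = 1e-2) {
  jit <- 0
  L <- tryCatch(chol(S), error = function(e) NULL)
  while (is.null(L)) {
    jit <- if (jit == 0) start * mean(diag(S)) else jit * 10
    if (jit > max_jitter * mean(diag(S)))
      stop(sprintf(
        "covariance not positive definite even after jitter %.3e", jit))
    L <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
  }
  L
}

# Quantiles of a weighted mixture of normals by bisection on the mixture CDF.
# means/sds: k-vectors (or n x k matrices for vectorized use), w: k weights.
mixtureQuantile <- function(p, means, sds, w, tol = 1e-6) {
  means <- rbind(means); sds <- rbind(sds)
  n <- nrow(means)
  lo <- apply(means - 10 * pmax(sds, 1e-12), 1, min)
  hi <- apply(means + 10 * pmax(sds, 1e-12), 1, max)
  cdf <- function(q) {
    z <- (q - means) / pmax(sds, 1e-300)
    as.vector(pnorm(z) %*% w)
  }
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    below <- cdf(mid) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

# Cache for the coarse-lattice field Cholesky: replicate loops redraw
# fields on the same grid and parameters, and the factor depends only on
# those, not on the seed. Bounded to a handful of configurations.
.fieldCholCache <- new.env(parent = emptyenv())

cachedFieldChol <- function(coords, params) {
  key <- paste(c("k", dim(coords), range(coords), params@sigma2,
                 params@rangeKm, params@nu), collapse = "|")
  if (exists(key, envir = .fieldCholCache, inherits = FALSE))
    return(get(key, envir = .fieldCholCache, inherits = FALSE))
  S <- params@sigma2 * maternCorrMatrix(coords, params@rangeKm, params@nu)
  L <- cholJitter(S)
  if (length(ls(.fieldCholCache)) >= 4)
    rm(list = ls(.fieldCholCache), envir = .fieldCholCache)
  assign(key, L, envir = .fieldCholCache)
  L
}
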