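#' Continuous CDF of the fitted compound distribution
#'
#' Mixture of continuous Poisson CDFs over the latent grid:
#' \eqn{F(x) = \sum_j e^{g_j} F_{pois}(x; e^{x_j}) / \sum_j e^{g_j}}.
#' Monotone increasing in `x` and tending to 1. Tail probabilities are
#' assembled on the log scale, so the survival function stays accurate far
#' into the tail where `1 - F(x)` underflows.
#'
#' @param x non-negative real values.
#' @param density a [LogConcaveDensity-class].
#' @param lower.tail,log.p as for standard distribution functions.
#' @return numeric vector of probabilities (or log-probabilities).
#' @export
pcompound <- function(x, density, lower.tail = TRUE, log.p = FALSE) {
  stopifnot2(all(x >= 0), "x must be >= 0")
  g <- density@g
  logw <- g - logSumExp(g)
  rates <- exp(gridPoints(density@grid))
  # log survival of the mixture: logsumexp over components
  out <- vapply(x, function(xi) {
    ls <- stats::pgamma(rates, shape = xi + 1, lower.tail = TRUE,
                        log.p = TRUE) # component log-survival
    logSumExp(logw + ls)
  }, numeric(1))
  if (lower.tail) {
    if (log.p) log1p(-exp(out)) else -expm1(out)
  } else {
    if (log.p) out else exp(out)
  }
}

#' Build the Poissonization transform for a fitted density
#'
#' Constructs the monotone map \eqn{t_k = F_{pois}^{-1}(F(k); \mu)} that
#' sends a raw count `k` through the fitted compound distribution's
#' continuous CDF and back through the continuous Poisson inverse CDF at
#' the target rate \eqn{\mu}. The free parameter \eqn{\mu} defaults to the
#' median of the latent rate distribution; any fixed choice yields an
#' equivalent (monotone) map, and an explicit `targetRate` can be supplied
#' for matched-rate cross-sample comparisons.
#'
#' The matching is performed on the log-survival scale, so counts deep in
#' the tail (where the compound CDF is numerically 1) transform without
#' overflow.
#'
#' @param density a [LogConcaveDensity-class] (typically
#'   `latentDensity(fitLogConcave(hist))`).
#' @param targetRate optional explicit Poisson reference rate.
#' @param kMax highest raw count precomputed in the table (defaults to 50;
#'   [adjustCount()] extends the table on demand).
#' @return a [TransformMap-class].
#' @examples
#' h <- countHistogram(rpois(5000, 2), totalBases = 5000)
#' map <- buildTransform(latentDensity(fitLogConcave(h, K = 256L)))
#' adjustCount(0:5, map)
#' @export
buildTransform <- function(density, targetRate = NULL, kMax = 50L) {
  stopifnot2(is(density, "LogConcaveDensity"),
             "'density' must be a LogConcaveDensity")
  mu <- if (is.null(targetRate)) targetRate(density) else as.numeric(targetRate)
  stopifnot2(mu > 0, "target rate must be > 0")
  tab <- .transformValues(0:kMax, density, mu)
  new("TransformMap", density = density, targetRate = mu, table = tab)
}

# core of the transform: quantile-match count k on the log-survival scale
.transformValues <- function(k, density, mu) {
  logS <- pcompound(k, density, lower.tail = FALSE, log.p = TRUE)
  t <- qcpois(logS, mu, lower.tail = FALSE, log.p = TRUE)
  # numerical safeguard: the exact map is strictly increasing, but two
  # adjacent k can collapse onto the root-finder tolerance; separate them
  if (length(t) > 1) for (i in 2:length(t))
    if (t[i] <= t[i - 1]) t[i] <- t[i - 1] + 1e-9
  t
}

#' Adjusted value of raw counts under a transform map
#'
#' Looks raw counts up in the precomputed `k -> t_k` table, extending the
#' table on demand for counts beyond its current range.
#'
#' @param k vector of non-negative integer raw counts.
#' @param map a [TransformMap-class].
#' @return numeric vector of adjusted (fractional) values.
#' @export
adjustCount <- function(k, map) {
  k <- as.integer(k)
  stopifnot2(all(k >= 0), "raw counts must be >= 0")
  tab <- map@table
  over <- k > length(tab) - 1L
  if (any(over)) {
    extra <- sort(unique(k[over]))
    vals <- .transformValues(extra, map@density, map@targetRate)
    full <- c(tab, rep(NA_real_, max(extra) - length(tab) + 1L))
    full[extra + 1L] <- vals
    tab <- full
  }
  tab[k + 1L]
}

#' Apply a transform map positionwise to per-base counts
#'
#' Replaces every raw count by its adjusted value; positions, ordering and
#' the domain size are untouched, so all joint structure of the data is
#' preserved and equal raw counts always receive equal adjusted values.
#'
#' The default deterministic probability integral transform evaluates the
#' compound CDF at the integer count. With `randomized = TRUE` each base
#' instead draws `u` uniformly on `[F(k-1), F(k)]` (the exact randomized
#' PIT of the discrete count) before inversion: distributionally closer to
#' the continuous reference but no longer a pure function of the count, so
#' equal raw counts may receive different adjusted values. The
#' deterministic default is recommended for reproducible pipelines.
#'
#' @param counts a [PerBaseCounts-class] with raw integer counts.
#' @param map a [TransformMap-class].
#' @param randomized use the randomized PIT (default `FALSE`).
#' @param seed integer seed for the randomized variant.
#' @return a [PerBaseCounts-class] with fractional values.
#' @export
applyTransform <- function(counts, map, randomized = FALSE, seed = NULL) {
  v <- baseValues(counts)
  if (any(v != round(v)))
    stop("applyTransform expects raw integer counts", call. = FALSE)
  k <- as.integer(round(v))
  gr <- counts@positions
  if (!randomized) {
    gr$score <- adjustCount(k, map)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    d <- map@density
    Fk <- pcompound(k, d)
    Fkm <- ifelse(k == 0, 0, pcompound(pmax(k - 1L, 0L), d))
    u <- Fkm + stats::runif(length(k)) * (Fk - Fkm)
    u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
    gr$score <- qcpois(u, map@targetRate)
  }
  new("PerBaseCounts", positions = gr, totalBases = counts@totalBases)
}
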