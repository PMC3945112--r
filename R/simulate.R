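#' Simulate per-base counts from a compound-Poisson model
#'
#' Draws a latent rate per base from the chosen family (optionally scaled
#' by `depthFactor`, emulating deeper sequencing of the same library) and
#' a Poisson count given the rate. Positions are laid out on a single
#' synthetic chromosome `"chrSim"` at `0 .. nBases - 1`. The true rates
#' are returned alongside the counts for recovery tests.
#'
#' Families: `"degenerate"` (all rates equal `exp(lambda)`, giving plain
#' Poisson counts), `"gamma"` (rates gamma with `shape`, `scale`: marginal
#' counts are negative binomial with dispersion index
#' `1 + scale * depthFactor`), `"lognormal"` (log-rates normal with
#' `meanlog`, `sdlog`), and `"tabulated"` (log-rates drawn from an
#' explicit density `g` on a [LatentGrid-class]).
#'
#' @param family latent family (see Details).
#' @param nBases number of bases simulated.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param depthFactor positive multiplier on all rates.
#' @param lambda log-rate of the degenerate family.
#' @param shape,scale gamma family parameters.
#' @param meanlog,sdlog lognormal family parameters.
#' @param grid,g tabulated family: latent grid and log-density values.
#' @return a list with elements `counts` (a [PerBaseCounts-class]) and
#'   `trueRates` (numeric, before depth scaling is applied to counts the
#'   rates already include `depthFactor`).
#' @examples
#' sim <- simulateCounts("gamma", nBases = 1000, seed = 1,
#'                       shape = 0.5, scale = 4)
#' dispersionIndex(sim$counts)
#' @export
simulateCounts <- function(family = c("degenerate", "gamma", "lognormal",
                                      "tabulated"),
                           nBases, seed = 1L, depthFactor = 1,
                           lambda = 0, shape = 1, scale = 1,
                           meanlog = 0, sdlog = 1, grid = NULL, g = NULL) {
  family <- match.arg(family)
  stopifnot2(nBases >= 1, "nBases must be >= 1")
  stopifnot2(depthFactor > 0, "depthFactor must be > 0")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rates <- switch(family,
    degenerate = rep(exp(lambda), nBases),
    gamma = {
      stopifnot2(shape > 0 && scale > 0, "gamma needs shape, scale > 0")
      stats::rgamma(nBases, shape = shape, scale = scale)
    },
    lognormal = {
      stopifnot2(sdlog > 0, "lognormal needs sdlog > 0")
      stats::rlnorm(nBases, meanlog = meanlog, sdlog = sdlog)
    },
    tabulated = {
      stopifnot2(!is.null(grid) && !is.null(g),
                 "tabulated family needs 'grid' and 'g'")
      x <- gridPoints(grid)
      w <- exp(g - max(g))
      j <- sample.int(length(x), nBases, replace = TRUE, prob = w)
      u <- stats::runif(nBases, -0.5, 0.5) # jitter within the cell
      exp(x[j] + u * gridStep(grid))
    })
  rates <- rates * depthFactor
  counts <- stats::rpois(nBases, rates)
  nz <- which(counts > 0)
  pbc <- PerBaseCounts(rep("chrSim", length(nz)), nz - 1L,
                       as.numeric(counts[nz]), totalBases = nBases)
  list(counts = pbc, trueRates = rates)
}

#' Simulate counts from the degenerate (de-duplication) model
#'
#' The generative model under which de-duplication is the exact
#' distribution-matching transform: each base is nonzero with probability
#' `pNonzero` and nonzero bases carry a uniform level on `1..maxCount`,
#' so all nonzero levels are equally probable.
#'
#' @param pNonzero probability a base has nonzero count, in `(0, 1)`.
#' @param maxCount upper bound of the uniform noise component.
#' @param nBases number of bases.
#' @param seed integer seed.
#' @return a [PerBaseCounts-class].
#' @export
simulateDedupDegenerate <- function(pNonzero, maxCount, nBases, seed = 1L) {
  stopifnot2(pNonzero > 0 && pNonzero < 1, "pNonzero must be in (0, 1)")
  stopifnot2(maxCount >= 1, "maxCount must be >= 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nz <- which(stats::runif(nBases) < pNonzero)
  lev <- sample.int(maxCount, length(nz), replace = TRUE)
  PerBaseCounts(rep("chrSim", length(nz)), nz - 1L, as.numeric(lev),
                totalBases = nBases)
}

#' @describeIn dispersionIndex variance/mean of a per-base dataset, zero
#'   bases included
#' @export
setMethod("dispersionIndex", "PerBaseCounts", function(x, ...) {
  N <- x@totalBases
  stopifnot2(N >= 2, "need at least 2 bases")
  v <- baseValues(x)
  s <- sum(v)
  stopifnot2(s > 0, "dispersion index is undefined for zero mean")
  m <- s / N
  ss <- sum(v^2)
  ((ss - N * m^2) / (N - 1)) / m
})

#' @describeIn dispersionIndex variance/mean of a plain numeric vector
#' @export
setMethod("dispersionIndex", "numeric", function(x, ...) {
  stopifnot2(length(x) >= 2, "need at least 2 values")
  m <- mean(x)
  stopifnot2(m > 0, "dispersion index is undefined for zero mean")
  stats::var(x) / m
})
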