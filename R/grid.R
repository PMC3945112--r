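#' Build a latent quadrature grid for a histogram
#'
#' The default span covers log-rates from well below one expected read in
#' the whole dataset, `log(0.5 / N)`, up to `log(max level) + 3`, three
#' e-folds above the largest observed count. Rates outside this window
#' contribute negligibly to the marginal likelihood of any observable
#' level.
#'
#' @param hist a [CountHistogram-class] with `N >= 1`.
#' @param K number of quadrature points (>= 3). The default, 4096, keeps
#'   quadrature error well below the statistical error of typical
#'   histograms; increase for very wide count ranges.
#' @param lo,hi optional explicit span overriding the default policy.
#' @return a [LatentGrid-class].
#' @examples
#' h <- countHistogram(rpois(1000, 2), totalBases = 1000)
#' makeLatentGrid(h, K = 512)
#' @export
makeLatentGrid <- function(hist, K = 4096L, lo = NULL, hi = NULL) {
  stopifnot2(is(hist, "CountHistogram"), "'hist' must be a CountHistogram")
  stopifnot2(hist@nBases >= 1, "histogram must cover at least one base")
  if (K < 3L) stop("grid needs K >= 3 quadrature points", call. = FALSE)
  maxk <- max(hist@level)
  if (is.null(lo)) lo <- log(0.5 / hist@nBases)
  if (is.null(hi)) hi <- log(max(maxk, 1L)) + 3
  new("LatentGrid", lo = as.numeric(lo), hi = as.numeric(hi),
      K = as.integer(K))
}

#' Poisson kernel matrix over a histogram's levels and a latent grid
#'
#' Entry `[k, j]` is `Pois(k | exp(x_j))`, the probability of the k-th
#' observed count level under the rate at grid point `j`. Computed in log
#' space to avoid underflow.
#'
#' @param hist a [CountHistogram-class].
#' @param grid a [LatentGrid-class].
#' @param log return the log-kernel (default `FALSE`).
#' @param levels optional integer vector of levels to use instead of the
#'   histogram's observed levels.
#' @return numeric matrix, rows = count levels, columns = grid points.
#' @export
poissonKernel <- function(hist, grid, log = FALSE, levels = NULL) {
  k <- if (is.null(levels)) hist@level else as.integer(levels)
  x <- gridPoints(grid)
  M <- outer(k, x) - rep(exp(x), each = length(k)) - lgamma(k + 1)
  dimnames(M) <- list(level = k, NULL)
  if (log) M else exp(M)
}
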