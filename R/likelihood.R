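# marginal likelihood of a count histogram under a latent log-concave
# density evaluated on a quadrature grid; quadrature weights cancel
# between the mixture sum and the normalizer, so neither appears here.

#' Marginal log-likelihood of a histogram under a latent log-density
#'
#' \deqn{L(g) = \sum_k c_k \log \sum_j P(k | e^{x_j}) e^{g_j}
#'              - N \log \sum_j e^{g_j}}
#' The value is invariant under adding a constant to `g` (the second term
#' normalizes the latent distribution).
#'
#' @param g numeric vector of log-density values on the grid (finite).
#' @param grid a [LatentGrid-class].
#' @param hist a [CountHistogram-class].
#' @param logKernel optional precomputed log-kernel from
#'   `poissonKernel(hist, grid, log = TRUE)`; computing it once speeds up
#'   repeated evaluation.
#' @return scalar log-likelihood (total over all `N` bases).
#' @export
marginalLogLik <- function(g, grid, hist, logKernel = NULL) {
  if (any(!is.finite(g))) stop("g must be finite", call. = FALSE)
  if (is.null(logKernel)) logKernel <- poissonKernel(hist, grid, log = TRUE)
  llk <- rowLogSumExp(logKernel + rep(g, each = nrow(logKernel)))
  sum(hist@count * llk) - hist@nBases * logSumExp(g)
}

#' Gradient of the marginal log-likelihood in `g`
#'
#' Component `j` is the difference between the posterior mass of grid
#' point `j` aggregated over the observed counts and the prior mass
#' predicted by the latent density alone:
#' \deqn{\partial L / \partial g_j =
#'   \sum_k c_k \frac{P_{kj} e^{g_j}}{\sum_{j'} P_{kj'} e^{g_{j'}}}
#'   - N \frac{e^{g_j}}{\sum_{j'} e^{g_{j'}}}}
#' Both terms total \eqn{N}, so the gradient components sum to zero.
#'
#' @inheritParams marginalLogLik
#' @return numeric vector of length `K`.
#' @export
logLikGradient <- function(g, grid, hist, logKernel = NULL) {
  if (any(!is.finite(g))) stop("g must be finite", call. = FALSE)
  if (is.null(logKernel)) logKernel <- poissonKernel(hist, grid, log = TRUE)
  M <- logKernel + rep(g, each = nrow(logKernel))
  llk <- rowLogSumExp(M)
  post <- exp(M - llk) # rows sum to 1
  w <- exp(g - logSumExp(g))
  as.numeric(crossprod(post, hist@count)) - hist@nBases * w
}

#' Marginal probability mass function of a fitted compound distribution
#'
#' \eqn{P(k) = \sum_j P(k | e^{x_j}) e^{g_j} / \sum_j e^{g_j}}. Sums to 1
#' over `k = 0, 1, ...` up to quadrature/truncation tolerance.
#'
#' @param density a [LogConcaveDensity-class].
#' @param k vector of non-negative integer count levels.
#' @return probabilities, one per element of `k`.
#' @export
marginalPmf <- function(density, k) {
  k <- as.integer(k)
  if (any(k < 0)) stop("count levels must be >= 0", call. = FALSE)
  x <- gridPoints(density@grid)
  g <- density@g
  logw <- g - logSumExp(g)
  logP <- outer(k, x) - rep(exp(x), each = length(k)) - lgamma(k + 1)
  exp(rowLogSumExp(logP + rep(logw, each = length(k))))
}

#' Latent distribution function and quantiles on the log-rate axis
#'
#' The fitted density assigns rectangle mass \eqn{w_j \propto e^{g_j}} to
#' the cell `[x_j - step/2, x_j + step/2]`; the CDF is piecewise linear
#' across cells and quantiles are its exact inverse.
#'
#' @param density a [LogConcaveDensity-class].
#' @param lambda log-rate values at which to evaluate the CDF.
#' @return probabilities (CDF) or log-rate values (quantile).
#' @export
latentCdf <- function(density, lambda) {
  x <- gridPoints(density@grid)
  step <- gridStep(density@grid)
  w <- exp(density@g - logSumExp(density@g))
  cw <- c(0, cumsum(w))
  edges <- c(x - step / 2, x[length(x)] + step / 2)
  idx <- findInterval(lambda, edges)
  out <- numeric(length(lambda))
  inside <- idx >= 1 & idx <= length(x)
  out[idx > length(x)] <- 1
  j <- idx[inside]
  out[inside] <- cw[j] + w[j] * (lambda[inside] - edges[j]) / step
  pmin(pmax(out, 0), 1)
}

#' @rdname latentCdf
#' @param p probabilities in `[0, 1]`.
#' @export
latentQuantile <- function(density, p) {
  stopifnot2(all(p >= 0 & p <= 1), "quantile levels must lie in [0, 1]")
  x <- gridPoints(density@grid)
  step <- gridStep(density@grid)
  w <- exp(density@g - logSumExp(density@g))
  cw <- cumsum(w)
  edges <- c(x - step / 2, x[length(x)] + step / 2)
  vapply(p, function(pp) {
    j <- which(cw >= pp - 1e-15)[1L]
    if (is.na(j)) return(edges[length(edges)])
    lo <- if (j == 1L) 0 else cw[j - 1L]
    edges[j] + step * (pp - lo) / w[j]
  }, numeric(1))
}

#' @describeIn targetRate median latent rate of a fitted density
#' @export
setMethod("targetRate", "LogConcaveDensity", function(object) {
  exp(latentQuantile(object, 0.5))
})

#' @export
setMethod("logLik", "LogConcaveDensity", function(object, hist, ...) {
  marginalLogLik(object@g, object@grid, hist)
})
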