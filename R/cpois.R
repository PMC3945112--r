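# Continuous extension of the Poisson distribution. The CDF at real
# x >= 0 is the regularized upper incomplete gamma function Q(x + 1, mu),
# which at integer x coincides with the ordinary Poisson CDF; the density
# is mu^x e^{-mu} / Gamma(x + 1). These are the building blocks of the
# Poissonization transform.

#' Continuous Poisson density, CDF and quantile function
#'
#' `dcpois()` evaluates \eqn{\mu^x e^{-\mu} / \Gamma(x+1)}; `pcpois()`
#' evaluates \eqn{Q(x + 1, \mu)} (so `pcpois(k, mu)` equals
#' `ppois(k, mu)` at integer `k`); `qcpois()` is the monotone numerical
#' inverse of `pcpois()` in `x`, solved by bracketed root-finding on the
#' log-survival scale so that quantile levels arbitrarily close to 1 stay
#' finite and accurate.
#'
#' @param x non-negative real values.
#' @param mu positive Poisson rate.
#' @param lower.tail,log.p as for standard distribution functions.
#' @param p probabilities in `(0, 1)` (or log-probabilities with
#'   `log.p = TRUE`).
#' @param tol root-finding tolerance for `qcpois()`.
#' @return numeric vector.
#' @examples
#' pcpois(0, 1)          # exp(-1)
#' qcpois(pcpois(3.7, 2), 2)
#' @export
dcpois <- function(x, mu) {
  stopifnot2(all(mu > 0), "mu must be > 0")
  stopifnot2(all(x >= 0), "x must be >= 0")
  exp(x * log(mu) - mu - lgamma(x + 1))
}

#' @rdname dcpois
#' @export
pcpois <- function(x, mu, lower.tail = TRUE, log.p = FALSE) {
  stopifnot2(all(mu > 0), "mu must be > 0")
  stopifnot2(all(x > -1), "x must exceed -1")
  # F(x) = Q(x + 1, mu) = upper tail of gamma(shape = x + 1) at mu
  stats::pgamma(mu, shape = x + 1, lower.tail = !lower.tail, log.p = log.p)
}

#' @rdname dcpois
#' @export
qcpois <- function(p, mu, lower.tail = TRUE, log.p = FALSE, tol = 1e-10) {
  stopifnot2(all(mu > 0), "mu must be > 0")
  logS <- if (log.p) {
    if (lower.tail) log1p(-exp(p)) else p
  } else {
    stopifnot2(all(p > 0 & p < 1), "p must lie in (0, 1)")
    if (lower.tail) log1p(-p) else log(p)
  }
  # solve log S(x) = logS; S(x) = P(X > x) is strictly decreasing in x
  vapply(seq_along(logS), function(i) {
    target <- logS[i]
    m <- if (length(mu) > 1) mu[i] else mu
    f <- function(x) pcpois(x, m, lower.tail = FALSE, log.p = TRUE) - target
    lo <- -1 + 1e-12
    hi <- m + 20 * sqrt(m) + 20
    while (f(hi) > 0) hi <- hi * 2 + 10
    if (f(lo) <= 0) return(0) # more survival at the left edge than target
    r <- stats::uniroot(f, c(lo, hi), tol = tol)$root
    max(r, 0)
  }, numeric(1))
}
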