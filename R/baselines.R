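# Parametric maximum-likelihood baselines and the per-base log-likelihood
# error diagnostic used to quantify overdispersion.

.poisLogLik <- function(hist, rate) {
  if (rate == 0) {
    if (any(hist@level > 0 & hist@count > 0)) return(-Inf)
    return(0)
  }
  sum(hist@count * stats::dpois(hist@level, rate, log = TRUE))
}

#' Poisson maximum-likelihood fit to a count histogram
#'
#' The MLE rate is the sample mean \eqn{\sum_k k c_k / N}. An all-zero
#' histogram yields the degenerate fit `rate = 0` with log-likelihood 0.
#'
#' @param hist a [CountHistogram-class].
#' @return a [ParametricFit-class] with parameter `rate`.
#' @export
fitPoisson <- function(hist) {
  rate <- sum(hist@level * hist@count) / hist@nBases
  new("ParametricFit", family = "poisson", params = c(rate = rate),
      logLik = .poisLogLik(hist, rate), atBoundary = FALSE, converged = TRUE)
}

#' De-duplicate a count histogram
#'
#' Collapses every level `k >= 1` onto level 1 — the histogram-level
#' equivalent of removing all but one read at each base. Idempotent.
#'
#' @param hist a [CountHistogram-class].
#' @return a [CountHistogram-class] with levels 0 and (possibly) 1.
#' @export
dedupHistogram <- function(hist) {
  nz <- sum(hist@count[hist@level > 0])
  CountHistogram(level = c(0L, 1L),
                 count = c(hist@nBases - nz, nz), nBases = hist@nBases)
}

#' Poisson fit to de-duplicated counts
#'
#' Applies [dedupHistogram()] and fits a Poisson to the result; the
#' log-likelihood is evaluated on the de-duplicated histogram. This is the
#' model implicitly assumed by callers that de-duplicate and then apply
#' Poisson statistics.
#'
#' @param hist a [CountHistogram-class] (raw, not yet de-duplicated).
#' @return a [ParametricFit-class] with family `"dedup_poisson"`.
#' @export
fitDedupPoisson <- function(hist) {
  dd <- dedupHistogram(hist)
  rate <- sum(dd@level * dd@count) / dd@nBases
  new("ParametricFit", family = "dedup_poisson", params = c(rate = rate),
      logLik = .poisLogLik(dd, rate), atBoundary = FALSE, converged = TRUE)
}

#' Negative binomial maximum-likelihood fit to a count histogram
#'
#' In the (size, mean) parameterization the MLE mean equals the sample
#' mean analytically, so only the size is profiled, by 1-d optimization of
#' the profile log-likelihood on the log scale. Underdispersed data (the
#' Poisson limit `size -> Inf`) are flagged `atBoundary` and returned with
#' the Poisson log-likelihood.
#'
#' @param hist a [CountHistogram-class] with positive sample mean.
#' @return a [ParametricFit-class] with parameters `size`, `mean` and the
#'   equivalent `prob` (`size / (size + mean)`).
#' @export
fitNegbin <- function(hist) {
  N <- hist@nBases
  m <- sum(hist@level * hist@count) / N
  stopifnot2(m > 0, "negative binomial fit needs a positive sample mean")
  s2 <- sum(hist@count * (hist@level - m)^2) / (N - 1)
  pll <- function(logSize)
    sum(hist@count * stats::dnbinom(hist@level, size = exp(logSize),
                                    mu = m, log = TRUE))
  poisLL <- .poisLogLik(hist, m)
  if (s2 <= m) { # Poisson limit
    return(new("ParametricFit", family = "negbin",
               params = c(size = Inf, mean = m, prob = 1),
               logLik = poisLL, atBoundary = TRUE, converged = TRUE))
  }
  init <- log(max(m^2 / (s2 - m), 1e-6)) # moment estimate
  opt <- stats::optimize(pll, lower = init - 15, upper = init + 15,
                         maximum = TRUE, tol = 1e-10)
  size <- exp(opt$maximum)
  bound <- opt$objective <= poisLL || opt$maximum >= init + 15 - 1e-6
  if (opt$objective < poisLL)
    return(new("ParametricFit", family = "negbin",
               params = c(size = Inf, mean = m, prob = 1),
               logLik = poisLL, atBoundary = TRUE, converged = TRUE))
  new("ParametricFit", family = "negbin",
      params = c(size = size, mean = m, prob = size / (size + m)),
      logLik = opt$objective, atBoundary = bound, converged = TRUE)
}

# marginal pmf of the log-normal-Poisson on given levels, by quadrature
# over the latent log-rate
.lnpoisLogPmf <- function(k, meanlog, sdlog, quadPoints = 257L) {
  x <- seq(meanlog - 8 * sdlog, meanlog + 8 * sdlog,
           length.out = quadPoints)
  step <- x[2] - x[1]
  logw <- stats::dnorm(x, meanlog, sdlog, log = TRUE) + log(step)
  M <- outer(k, x) - rep(exp(x), each = length(k)) - lgamma(k + 1)
  rowLogSumExp(M + rep(logw, each = length(k)))
}

#' Log-normal-Poisson maximum-likelihood fit
#'
#' Compound model in which per-base log-rates are normal with parameters
#' `meanlog`, `sdlog`; the marginal likelihood is approximated by
#' quadrature on the latent axis and maximized numerically from several
#' seeded random restarts around a moment-based initialization.
#'
#' @param hist a [CountHistogram-class].
#' @param restarts number of random initializations.
#' @param quadPoints quadrature points on the latent normal axis.
#' @param seed integer seed for the restart draws.
#' @return a [ParametricFit-class] with parameters `meanlog`, `sdlog`.
#' @export
fitLognormalPoisson <- function(hist, restarts = 10L, quadPoints = 257L,
                                seed = 1L) {
  N <- hist@nBases
  m <- max(sum(hist@level * hist@count) / N, 0.5 / N)
  s2 <- sum(hist@count * (hist@level - m)^2) / max(N - 1, 1)
  # moment inversion: Var/mean - 1 = m (e^{sig2} - 1)
  sig2 <- log1p(max(s2 / m - 1, 0.01) / m)
  sig2 <- min(max(sig2, 1e-3), 25)
  init0 <- c(log(m) - sig2 / 2, log(sqrt(sig2)))
  nll <- function(par) {
    sdl <- exp(par[2])
    if (!is.finite(sdl) || sdl > 50) return(1e10)
    lp <- .lnpoisLogPmf(hist@level, par[1], sdl, quadPoints)
    v <- -sum(hist@count * lp)
    if (!is.finite(v)) 1e10 else v
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) init0 else init0 + stats::rnorm(2, 0, 0.5)
    opt <- tryCatch(
      stats::optim(init, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  stopifnot2(!is.null(best), "log-normal-Poisson optimization failed")
  new("ParametricFit", family = "lognormal_poisson",
      params = c(meanlog = best$par[1], sdlog = exp(best$par[2])),
      logLik = -best$value, atBoundary = FALSE,
      converged = best$convergence == 0)
}

#' @describeIn modelPmf pmf of a parametric baseline fit (for
#'   `"dedup_poisson"` this is the Poisson pmf on the de-duplicated scale)
#' @export
setMethod("modelPmf", "ParametricFit", function(object) {
  p <- object@params
  switch(object@family,
    poisson = ,
    dedup_poisson = function(k) stats::dpois(k, p[["rate"]]),
    negbin = if (is.infinite(p[["size"]]))
      function(k) stats::dpois(k, p[["mean"]])
    else
      function(k) stats::dnbinom(k, size = p[["size"]], mu = p[["mean"]]),
    lognormal_poisson = function(k)
      exp(.lnpoisLogPmf(as.integer(k), p[["meanlog"]], p[["sdlog"]])))
})

#' @describeIn modelPmf marginal pmf of a fitted latent density
#' @export
setMethod("modelPmf", "LogConcaveDensity", function(object) {
  function(k) marginalPmf(object, k)
})

.logLikErrorCore <- function(hist, pmfFun) {
  keep <- hist@count > 0
  lev <- hist@level[keep]
  ck <- hist@count[keep]
  p <- pmfFun(lev)
  e <- log(ck / hist@nBases) - log(p)
  e[p <= 0] <- Inf
  new("LogLikErrorProfile", level = lev, error = e,
      meanError = sum((ck / hist@nBases) * e))
}

#' @describeIn logLikError compare against an arbitrary vectorized pmf
#' @export
setMethod("logLikError", signature("CountHistogram", "function"),
          function(hist, model, ...) .logLikErrorCore(hist, model))

#' @describeIn logLikError compare against a parametric baseline fit; for
#'   family `"dedup_poisson"` the empirical side is de-duplicated first,
#'   matching how such pipelines see the data
#' @export
setMethod("logLikError", signature("CountHistogram", "ParametricFit"),
          function(hist, model, ...) {
            h <- if (model@family == "dedup_poisson") dedupHistogram(hist)
                 else hist
            .logLikErrorCore(h, modelPmf(model))
          })

#' @describeIn logLikError compare against a fitted latent density
#' @export
setMethod("logLikError", signature("CountHistogram", "LogConcaveDensity"),
          function(hist, model, ...) .logLikErrorCore(hist, modelPmf(model)))
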