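#' @importClassesFrom GenomicRanges GRanges
NULL

#' Reduce per-base counts to a count histogram
#'
#' Tabulates the number of bases at each count level. Defined only for raw
#' integer counts; fractional (adjusted) values are rejected because the
#' histogram is the sufficient statistic of the *raw* data.
#'
#' @param x a [PerBaseCounts-class], or a numeric vector of raw counts.
#' @param ... further arguments; for the numeric method, `totalBases`.
#' @return a [CountHistogram-class].
#' @examples
#' countHistogram(c(1, 1, 2), totalBases = 10)
#' @export
setGeneric("countHistogram", function(x, ...) standardGeneric("countHistogram"))

#' Total number of bases in the considered domain
#' @param x a [PerBaseCounts-class] or [CountHistogram-class].
#' @return integer-valued scalar.
#' @export
setGeneric("totalBases", function(x) standardGeneric("totalBases"))

#' Per-base values (counts or adjusted counts)
#' @param x a [PerBaseCounts-class].
#' @return numeric vector of stored (nonzero-position) values.
#' @export
setGeneric("baseValues", function(x) standardGeneric("baseValues"))

#' Index of dispersion (variance / mean)
#'
#' Sample variance over sample mean of the per-base counts, zero bases
#' included. Equals 1 in expectation for Poisson data; values well above 1
#' quantify overdispersion.
#'
#' @param x a [PerBaseCounts-class] or numeric vector.
#' @param ... unused.
#' @return positive scalar.
#' @export
setGeneric("dispersionIndex", function(x, ...) standardGeneric("dispersionIndex"))

#' Poisson reference rate of a transform
#'
#' For a [LogConcaveDensity-class] this computes the free parameter of the
#' Poissonization map: the median of the latent *rate* distribution,
#' obtained as `exp()` of the interpolated median on the log-rate grid.
#' For a [TransformMap-class] it returns the rate the map was built with.
#'
#' @param object a fitted density or transform map.
#' @return positive scalar rate \eqn{\mu}.
#' @export
setGeneric("targetRate", function(object) standardGeneric("targetRate"))

#' Per-level log-likelihood error profile
#'
#' Compares the empirical count frequencies against a model pmf:
#' \eqn{e_k = \log(c_k/N) - \log P_{model}(k)} at every observed level,
#' plus the per-base mean error (the empirical-to-model KL divergence).
#' Levels the model assigns zero probability get `Inf`, reported rather
#' than raised.
#'
#' @param hist a [CountHistogram-class].
#' @param model a vectorized pmf `function(k)`, a [ParametricFit-class], or
#'   a [LogConcaveDensity-class].
#' @param ... unused.
#' @return a [LogLikErrorProfile-class].
#' @export
setGeneric("logLikError", function(hist, model, ...) standardGeneric("logLikError"))

#' Model pmf as a function of the count level
#'
#' @param object a [ParametricFit-class] or [LogConcaveDensity-class].
#' @return a vectorized `function(k)` returning probabilities.
#' @export
setGeneric("modelPmf", function(object) standardGeneric("modelPmf"))

#' @export
setGeneric("logLik")

#' Fitted latent density of a fit object
#' @param object a [LogConcaveFit-class] or [TransformMap-class].
#' @return a [LogConcaveDensity-class].
#' @export
setGeneric("latentDensity", function(object) standardGeneric("latentDensity"))
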