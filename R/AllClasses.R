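#' CountHistogram: sufficient statistic of a per-base count dataset
#'
#' Stores, for each observed count level \eqn{k}, the number of bases
#' \eqn{c_k} that carry exactly \eqn{k} reads, together with the total
#' number of bases \eqn{N} in the (mappable) domain. All model fitting in
#' fixcount operates on this object, so the cost of inference is
#' independent of genome size. Level 0 is always stored explicitly;
#' \eqn{c_0 = N - \sum_{k \ge 1} c_k}.
#'
#' @slot level integer vector of distinct count levels (sorted, includes 0).
#' @slot count numeric vector of base counts \eqn{c_k} per level.
#' @slot nBases total number of bases \eqn{N}.
#'
#' @seealso [countHistogram()], [readCountHistogram()]
#' @export
setClass("CountHistogram",
  representation(level = "integer", count = "numeric", nBases = "numeric"),
  prototype(level = 0L, count = 0, nBases = 0),
  validity = function(object) {
    msg <- NULL
    if (length(object@level) != length(object@count))
      msg <- c(msg, "'level' and 'count' must have equal length")
    if (any(object@level < 0L)) msg <- c(msg, "count levels must be >= 0")
    if (anyDuplicated(object@level)) msg <- c(msg, "count levels must be unique")
    if (is.unsorted(object@level)) msg <- c(msg, "count levels must be sorted")
    if (any(object@count < 0)) msg <- c(msg, "all c_k must be >= 0")
    if (any(object@count != round(object@count)))
      msg <- c(msg, "all c_k must be integers")
    if (!isTRUE(all.equal(sum(object@count), object@nBases)))
      msg <- c(msg, "sum of c_k must equal total bases N")
    if (!(0L %in% object@level))
      msg <- c(msg, "level 0 must be stored explicitly")
    if (is.null(msg)) TRUE else msg
  })

#' PerBaseCounts: per-base read counts over genomic positions
#'
#' A thin container pairing width-1 genomic positions (a
#' [GenomicRanges::GRanges] with a `score` column holding the count, raw
#' integer or fractional after adjustment) with the size of the considered
#' mappable domain. Zero-count bases are not stored; they are implied by
#' `totalBases`.
#'
#' @slot positions GRanges of width-1 positions; `score` holds the value.
#' @slot totalBases size of the considered domain including zero bases.
#'
#' @seealso [readBedGraph()], [countHistogram()], [applyTransform()]
#' @export
setClass("PerBaseCounts",
  representation(positions = "GRanges", totalBases = "numeric"),
  validity = function(object) {
    msg <- NULL
    gr <- object@positions
    if (length(gr) > 0 && !all(GenomicRanges::width(gr) == 1L))
      msg <- c(msg, "all positions must have width 1")
    v <- baseValues(object)
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "all values must be finite and >= 0")
    if (sum(v > 0) > object@totalBases)
      msg <- c(msg, "more nonzero bases than totalBases")
    if (anyDuplicated(paste0(GenomicRanges::seqnames(gr), ":",
                             GenomicRanges::start(gr))))
      msg <- c(msg, "positions must be unique per chromosome")
    if (is.null(msg)) TRUE else msg
  })

#' LatentGrid: uniform quadrature grid on the log-rate axis
#'
#' The mixture integral over latent Poisson log-rates is approximated by a
#' sum over `K` uniformly spaced quadrature points on `[lo, hi]`
#' (midpoint/rectangle weights). Because quadrature weights cancel between
#' the numerator and the normalizer of the marginal likelihood, the fit
#' depends on the grid only through its resolution and span.
#'
#' @slot lo,hi grid endpoints on the log-rate axis.
#' @slot K number of quadrature points (>= 3).
#' @export
setClass("LatentGrid",
  representation(lo = "numeric", hi = "numeric", K = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@K < 3L) msg <- c(msg, "grid needs K >= 3 points")
    if (!is.finite(object@lo) || !is.finite(object@hi) ||
        object@hi <= object@lo)
      msg <- c(msg, "grid requires finite lo < hi")
    if (is.null(msg)) TRUE else msg
  })

#' LogConcaveDensity: concave log-density on a latent grid
#'
#' Values \eqn{g_j} of a concave log-density evaluated at the grid points,
#' pinned so that \eqn{\max_j g_j = 0} (the normalizer absorbs the scale).
#' `logZ` caches \eqn{\log \sum_j e^{g_j} \Delta}. Concavity is enforced
#' to a tolerance of \eqn{10^{-8}} scaled by the magnitude of `g`
#' (floating-point projection cannot do better on vectors spanning
#' hundreds of log units).
#'
#' @slot grid the [LatentGrid-class] the density lives on.
#' @slot g numeric vector of log-density values, one per grid point.
#' @slot logZ log normalization constant.
#' @export
setClass("LogConcaveDensity",
  representation(grid = "LatentGrid", g = "numeric", logZ = "numeric"),
  validity = function(object) {
    msg <- NULL
    K <- object@grid@K
    if (length(object@g) != K)
      msg <- c(msg, "length(g) must equal grid size K")
    if (any(!is.finite(object@g))) msg <- c(msg, "g must be finite")
    if (length(object@g) >= 3) {
      d2 <- diff(object@g, differences = 2)
      tolc <- 1e-8 * max(1, max(abs(object@g)))
      if (max(d2) > tolc)
        msg <- c(msg, sprintf("g is not concave (max second difference %.3g)",
                              max(d2)))
    }
    if (abs(max(object@g)) > 1e-8)
      msg <- c(msg, "g must be pinned at max(g) = 0")
    if (is.null(msg)) TRUE else msg
  })

#' LogConcaveFit: result of the latent log-concave fit
#'
#' @slot density the fitted [LogConcaveDensity-class].
#' @slot logLikTrace best-so-far marginal log-likelihood per iteration.
#' @slot logLik marginal log-likelihood at the returned solution.
#' @slot converged whether the stopping rule was met within `maxIter`.
#' @slot nIter number of proximal-gradient iterations performed.
#' @seealso [fitLogConcave()]
#' @export
setClass("LogConcaveFit",
  representation(density = "LogConcaveDensity", logLikTrace = "numeric",
                 logLik = "numeric", converged = "logical", nIter = "integer"))

#' ParametricFit: maximum-likelihood parametric baseline fit
#'
#' @slot family one of `"poisson"`, `"negbin"`, `"lognormal_poisson"`,
#'   `"dedup_poisson"`.
#' @slot params named numeric parameter vector (family specific).
#' @slot logLik total log-likelihood on the histogram used for fitting.
#' @slot atBoundary `TRUE` if the optimum sits on a parameter-space
#'   boundary (e.g. negative binomial `size` diverging on underdispersed
#'   data).
#' @slot converged optimizer convergence flag.
#' @export
setClass("ParametricFit",
  representation(family = "character", params = "numeric", logLik = "numeric",
                 atBoundary = "logical", converged = "logical"),
  validity = function(object) {
    fam <- object@family
    ok <- fam %in% c("poisson", "negbin", "lognormal_poisson", "dedup_poisson")
    if (!ok) return("unknown family")
    p <- object@params
    if (fam %in% c("poisson", "dedup_poisson") && p[["rate"]] < 0)
      return("poisson rate must be >= 0")
    if (fam == "negbin" && (p[["size"]] <= 0 || p[["mean"]] <= 0))
      return("negbin needs size > 0 and mean > 0")
    if (fam == "lognormal_poisson" && p[["sdlog"]] <= 0)
      return("lognormal_poisson needs sdlog > 0")
    TRUE
  })

#' TransformMap: monotone map from raw to Poisson-calibrated counts
#'
#' Precomputed table `k -> t_k` sending each raw count through the fitted
#' compound distribution's continuous CDF and the continuous Poisson
#' inverse CDF at the target rate. The map is strictly increasing, so rank
#' order among distinct counts is always preserved.
#'
#' @slot density the fitted latent density behind the map.
#' @slot targetRate the Poisson reference rate \eqn{\mu} (defaults to the
#'   median of the latent rate distribution).
#' @slot table adjusted values `t_k` for `k = 0 .. length(table) - 1`.
#' @seealso [buildTransform()], [adjustCount()]
#' @export
setClass("TransformMap",
  representation(density = "LogConcaveDensity", targetRate = "numeric",
                 table = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@targetRate <= 0) msg <- c(msg, "targetRate must be > 0")
    if (any(object@table < 0)) msg <- c(msg, "adjusted values must be >= 0")
    if (length(object@table) > 1 && any(diff(object@table) <= 0))
      msg <- c(msg, "transform table must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' LogLikErrorProfile: per-level log-likelihood error diagnostic
#'
#' For every level with \eqn{c_k > 0}, the error
#' \eqn{e_k = \log(c_k / N) - \log P_{model}(k)}: positive where the model
#' underestimates how many bases carry \eqn{k} reads. `meanError` is the
#' per-base average \eqn{(1/N) \sum_k c_k e_k}, i.e. the KL divergence from
#' the empirical count distribution to the model.
#'
#' @slot level observed count levels.
#' @slot error per-level errors \eqn{e_k} (may be `Inf` where the model
#'   assigns zero probability).
#' @slot meanError per-base mean error.
#' @seealso [logLikError()]
#' @export
setClass("LogLikErrorProfile",
  representation(level = "integer", error = "numeric", meanError = "numeric"))
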