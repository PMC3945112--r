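#' Construct a CountHistogram from levels and counts
#'
#' Low-level constructor; most users will call [countHistogram()] on data
#' or [readCountHistogram()] on a file. Level 0 is added (or completed)
#' automatically so that `sum(counts)` equals `nBases` when given.
#'
#' @param level non-negative integer count levels.
#' @param count number of bases at each level.
#' @param nBases total bases; when larger than `sum(count)` the difference
#'   is assigned to level 0.
#' @return a [CountHistogram-class].
#' @export
CountHistogram <- function(level, count, nBases = sum(count)) {
  level <- as.integer(level)
  count <- as.numeric(count)
  keep <- order(level)
  level <- level[keep]; count <- count[keep]
  if (!0L %in% level) { level <- c(0L, level); count <- c(0, count) }
  extra <- nBases - sum(count)
  if (extra < -1e-9) stop("nBases is smaller than the number of tabulated bases")
  count[level == 0L] <- count[level == 0L] + extra
  new("CountHistogram", level = level, count = count, nBases = as.numeric(nBases))
}

#' Construct a PerBaseCounts object
#'
#' @param chrom chromosome names (recycled).
#' @param pos 0-based base positions.
#' @param value non-negative per-base values.
#' @param totalBases size of the considered domain (defaults to the number
#'   of records).
#' @return a [PerBaseCounts-class].
#' @export
PerBaseCounts <- function(chrom = character(), pos = integer(),
                          value = numeric(), totalBases = length(pos)) {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = as.numeric(pos) + 1, width = 1), score = value)
  new("PerBaseCounts", positions = gr, totalBases = as.numeric(totalBases))
}

#' @describeIn totalBases total bases of a histogram
#' @export
setMethod("totalBases", "CountHistogram", function(x) x@nBases)

#' @describeIn totalBases domain size of a per-base dataset
#' @export
setMethod("totalBases", "PerBaseCounts", function(x) x@totalBases)

#' @describeIn baseValues stored values of a per-base dataset
#' @export
setMethod("baseValues", "PerBaseCounts",
          function(x) as.numeric(x@positions$score))

#' Genomic positions of a PerBaseCounts object
#' @param x a [PerBaseCounts-class].
#' @return a `GRanges` of width-1 positions with a `score` column.
#' @export
positionRanges <- function(x) x@positions

#' Observed count levels and per-level base counts
#' @param x a [CountHistogram-class].
#' @return integer (levels) or numeric (counts) vector.
#' @export
histLevels <- function(x) x@level

#' @rdname histLevels
#' @export
histCounts <- function(x) x@count

#' Quadrature points of a latent grid
#' @param grid a [LatentGrid-class].
#' @return numeric vector of `K` log-rate values.
#' @export
gridPoints <- function(grid) seq(grid@lo, grid@hi, length.out = grid@K)

#' @rdname gridPoints
#' @export
gridStep <- function(grid) (grid@hi - grid@lo) / (grid@K - 1L)

#' @rdname gridPoints
#' @export
gridSize <- function(grid) grid@K

#' Log-density values of a fitted latent density
#' @param density a [LogConcaveDensity-class].
#' @return numeric vector `g` (pinned at `max(g) = 0`).
#' @export
latentLogDensity <- function(density) density@g

#' @rdname latentLogDensity
#' @export
latentGrid <- function(density) density@grid

#' @describeIn latentDensity density of a completed fit
#' @export
setMethod("latentDensity", "LogConcaveFit", function(object) object@density)

#' @describeIn latentDensity density behind a transform map
#' @export
setMethod("latentDensity", "TransformMap", function(object) object@density)

#' Convergence flag of a fit
#' @param fit a [LogConcaveFit-class].
#' @return logical.
#' @export
converged <- function(fit) fit@converged

#' @rdname converged
#' @export
nIterations <- function(fit) fit@nIter

#' Best-so-far objective trace of a fit
#' @param fit a [LogConcaveFit-class].
#' @return numeric vector, one value per iteration.
#' @export
logLikTrace <- function(fit) fit@logLikTrace

#' @export
setMethod("logLik", "LogConcaveFit", function(object, ...) object@logLik)

#' @export
setMethod("logLik", "ParametricFit", function(object, ...) object@logLik)

#' Parameters of a parametric baseline fit
#' @param fit a [ParametricFit-class].
#' @return named numeric vector.
#' @export
fitParams <- function(fit) fit@params

#' @rdname fitParams
#' @export
fitFamily <- function(fit) fit@family

#' @rdname fitParams
#' @export
atBoundary <- function(fit) fit@atBoundary

#' Adjusted-value table of a transform map
#' @param map a [TransformMap-class].
#' @return numeric vector `t_k`, `k = 0 .. length - 1`.
#' @export
transformTable <- function(map) map@table

#' @describeIn targetRate rate stored in a transform map
#' @export
setMethod("targetRate", "TransformMap", function(object) object@targetRate)

#' Per-level errors of a diagnostic profile
#' @param profile a [LogLikErrorProfile-class].
#' @return numeric vector (or scalar for `meanLogLikError`).
#' @export
errorByLevel <- function(profile) stats::setNames(profile@error,
                                                  profile@level)

#' @rdname errorByLevel
#' @export
meanLogLikError <- function(profile) profile@meanError

setMethod("show", "CountHistogram", function(object) {
  cat(sprintf("CountHistogram: %s bases, %d levels, max count %d\n",
              format(object@nBases, big.mark = ","), length(object@level),
              max(object@level)))
  cat(sprintf("  mean count %.4g, fraction nonzero %.4g\n",
              sum(object@level * object@count) / object@nBases,
              1 - object@count[object@level == 0L] / object@nBases))
})

setMethod("show", "PerBaseCounts", function(object) {
  cat(sprintf("PerBaseCounts: %d nonzero positions over %s bases\n",
              length(object@positions),
              format(object@totalBases, big.mark = ",")))
  if (length(object@positions) > 0)
    cat(sprintf("  value range [%.4g, %.4g]\n",
                min(object@positions$score), max(object@positions$score)))
})

setMethod("show", "LatentGrid", function(object) {
  cat(sprintf("LatentGrid: K = %d points on [%.4g, %.4g], step %.4g\n",
              object@K, object@lo, object@hi, gridStep(object)))
})

setMethod("show", "LogConcaveDensity", function(object) {
  cat(sprintf("LogConcaveDensity on %d-point grid [%.4g, %.4g]\n",
              object@grid@K, object@grid@lo, object@grid@hi))
  cat(sprintf("  median latent rate %.4g\n", targetRate(object)))
})

setMethod("show", "LogConcaveFit", function(object) {
  cat(sprintf("LogConcaveFit: logLik %.6g after %d iterations (%s)\n",
              object@logLik, object@nIter,
              if (object@converged) "converged" else "not converged"))
  show(object@density)
})

setMethod("show", "ParametricFit", function(object) {
  cat(sprintf("ParametricFit [%s]: logLik %.6g%s\n", object@family,
              object@logLik, if (object@atBoundary) " (at boundary)" else ""))
  print(object@params)
})

setMethod("show", "TransformMap", function(object) {
  cat(sprintf("TransformMap: target rate %.4g, table for k = 0..%d\n",
              object@targetRate, length(object@table) - 1L))
  k <- seq_len(min(6L, length(object@table))) - 1L
  cat("  ", paste(sprintf("%d -> %.3f", k, object@table[k + 1L]),
                  collapse = ", "), "\n")
})

setMethod("show", "LogLikErrorProfile", function(object) {
  cat(sprintf("LogLikErrorProfile over %d levels, per-base mean error %.4g\n",
              length(object@level), object@meanError))
})
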