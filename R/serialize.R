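#' Save and load a fitted model as JSON
#'
#' The serialized model carries the grid, the log-density values, the log
#' normalizer and a metadata block (package version, fit options and the
#' reached log-likelihood when saving a [LogConcaveFit-class]), so a
#' transform can be applied later without refitting.
#'
#' @param object a [LogConcaveFit-class] or [LogConcaveDensity-class].
#' @param path output JSON file.
#' @param meta optional named list merged into the metadata block.
#' @return `path` (write) or a [LogConcaveDensity-class] (read); when the
#'   file was written from a fit, the metadata is attached as attribute
#'   `"meta"`.
#' @export
writeModel <- function(object, path, meta = list()) {
  density <- if (is(object, "LogConcaveFit")) object@density else object
  stopifnot2(is(density, "LogConcaveDensity"),
             "'object' must be a LogConcaveFit or LogConcaveDensity")
  if (is(object, "LogConcaveFit"))
    meta <- c(meta, list(logLik = object@logLik, converged = object@converged,
                         nIter = object@nIter))
  meta$version <- as.character(utils::packageVersion("fixcount"))
  payload <- list(
    grid = list(lo = density@grid@lo, hi = density@grid@hi,
                K = density@grid@K),
    g = density@g,
    logZ = density@logZ,
    meta = meta)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17)),
             path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  payload <- jsonlite::fromJSON(path)
  grid <- new("LatentGrid", lo = payload$grid$lo, hi = payload$grid$hi,
              K = as.integer(payload$grid$K))
  density <- new("LogConcaveDensity", grid = grid,
                 g = as.numeric(payload$g), logZ = payload$logZ)
  attr(density, "meta") <- payload$meta
  density
}
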