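#' Overdispersion diagnostics for a count histogram
#'
#' Fits the parametric baselines (Poisson, de-duplicated Poisson, negative
#' binomial, log-normal-Poisson) and optionally the nonparametric latent
#' log-concave model, and computes the per-level log-likelihood error
#' profile of each: how strongly each model misstates the observed number
#' of bases at each count level, and on average per base. The per-base
#' mean error of the Poisson is exactly the error incurred by a
#' Poisson-assuming significance calculation on these data.
#'
#' @param hist a [CountHistogram-class].
#' @param logconcave include the log-concave fit (slower; default `TRUE`).
#' @param K grid size for the log-concave fit.
#' @param restarts restarts for the log-normal-Poisson fit.
#' @param seed seed for the randomized restarts.
#' @return a list with elements `fits` (named list of fit objects),
#'   `profiles` (named list of [LogLikErrorProfile-class]), and
#'   `meanErrors` (named numeric vector).
#' @export
overdispersionDiagnostics <- function(hist, logconcave = TRUE, K = 1024L,
                                      restarts = 10L, seed = 1L) {
  fits <- list(
    poisson = fitPoisson(hist),
    dedup_poisson = fitDedupPoisson(hist),
    negbin = fitNegbin(hist),
    lognormal_poisson = fitLognormalPoisson(hist, restarts = restarts,
                                            seed = seed))
  if (logconcave)
    fits$logconcave <- fitLogConcave(hist, K = K)
  profiles <- lapply(fits, function(f) {
    model <- if (is(f, "LogConcaveFit")) f@density else f
    logLikError(hist, model)
  })
  list(fits = fits, profiles = profiles,
       meanErrors = vapply(profiles, meanLogLikError, numeric(1)))
}

#' Write a diagnostics report as TSV and JSON
#'
#' The TSV holds one row per (model, count level) with the per-level error
#' `e_k`; the JSON summarizes per-base mean errors, fitted parameters and
#' log-likelihoods.
#'
#' @param report result of [overdispersionDiagnostics()].
#' @param tsvPath,jsonPath output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the paths written.
#' @export
writeDiagnostics <- function(report, tsvPath = NULL, jsonPath = NULL) {
  if (!is.null(tsvPath)) {
    rows <- do.call(rbind, lapply(names(report$profiles), function(nm) {
      p <- report$profiles[[nm]]
      data.frame(model = nm, level = p@level, error = p@error)
    }))
    utils::write.table(rows, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(jsonPath)) {
    summ <- lapply(names(report$fits), function(nm) {
      f <- report$fits[[nm]]
      if (is(f, "LogConcaveFit"))
        list(logLik = f@logLik, converged = f@converged, nIter = f@nIter,
             meanError = unname(report$meanErrors[[nm]]))
      else
        list(logLik = f@logLik, params = as.list(f@params),
             atBoundary = f@atBoundary,
             meanError = unname(report$meanErrors[[nm]]))
    })
    names(summ) <- names(report$fits)
    writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA),
               jsonPath)
  }
  invisible(list(tsv = tsvPath, json = jsonPath))
}

#' Log-scale count histogram plot, before/after correction
#'
#' Plots `log10(c_k)` against the count level for one or more histograms
#' (e.g. raw counts and rounded adjusted counts). Poisson-distributed
#' counts with a small rate fall close to a straight line on this scale;
#' overdispersion shows up as a heavy, curved tail.
#'
#' @param ... one or more [CountHistogram-class] objects (named arguments
#'   become legend labels).
#' @param main plot title.
#' @export
plotCountHistogram <- function(..., main = "per-base count histogram") {
  hists <- list(...)
  if (is.null(names(hists)) || any(names(hists) == ""))
    names(hists) <- paste0("hist", seq_along(hists))
  cols <- seq_along(hists)
  xmax <- max(vapply(hists, function(h) max(h@level), numeric(1)))
  ymax <- max(vapply(hists, function(h) log10(max(h@count)), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = "count level k", ylab = "log10 c_k", main = main)
  for (i in seq_along(hists)) {
    h <- hists[[i]]
    keep <- h@count > 0
    graphics::points(h@level[keep], log10(h@count[keep]), col = cols[i],
                     pch = 19, cex = 0.6)
  }
  graphics::legend("topright", legend = names(hists), col = cols, pch = 19)
}
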