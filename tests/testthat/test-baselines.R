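test_that("Poisson MLE is the sample mean, with degenerate all-zero handling", {
  h <- CountHistogram(level = c(0L, 1L, 2L), count = c(2, 1, 1), nBases = 4)
  f <- fitPoisson(h)
  expect_equal(unname(fitParams(f)[["rate"]]), 0.75)
  expect_equal(logLik(f),
               sum(histCounts(h) * dpois(histLevels(h), 0.75, log = TRUE)))
  z <- fitPoisson(CountHistogram(level = 0L, count = 5, nBases = 5))
  expect_equal(unname(fitParams(z)[["rate"]]), 0)
  expect_equal(logLik(z), 0)
})

test_that("de-duplication collapses positive levels and is idempotent", {
  h <- CountHistogram(level = c(0L, 1L, 2L), count = c(7, 2, 1), nBases = 10)
  d <- dedupHistogram(h)
  expect_equal(histLevels(d), c(0L, 1L))
  expect_equal(histCounts(d), c(7, 3))
  expect_equal(histCounts(dedupHistogram(d)), histCounts(d))
  z <- CountHistogram(level = 0L, count = 5, nBases = 5)
  expect_equal(histCounts(dedupHistogram(z))[1], 5)
})

test_that("negative binomial MLE keeps the sample mean and nests the Poisson", {
  sim <- simulateCounts("gamma", nBases = 30000, seed = 71,
                        shape = 2, scale = 0.5)
  h <- countHistogram(sim$counts)
  nb <- fitNegbin(h)
  m <- sum(histLevels(h) * histCounts(h)) / totalBases(h)
  expect_equal(unname(fitParams(nb)[["mean"]]), m, tolerance = 1e-9)
  expect_gte(logLik(nb), logLik(fitPoisson(h)))
  expect_false(atBoundary(nb))

  # equidispersed data land on the Poisson boundary
  hp <- poisHist(n = 20000, rate = 1, seed = 72)
  nbp <- fitNegbin(hp)
  expect_true(atBoundary(nbp))
  expect_equal(logLik(nbp), logLik(fitPoisson(hp)), tolerance = 1e-6)
})

test_that("log-normal-Poisson tends to the Poisson fit on equidispersed data", {
  h <- poisHist(n = 20000, rate = 2, seed = 73)
  lf <- fitLognormalPoisson(h, restarts = 4L, seed = 1)
  expect_gte(logLik(lf), logLik(fitPoisson(h)) - 1e-3 * totalBases(h))
})

test_that("log-likelihood error profiles behave as diagnostics", {
  sim <- simulateCounts("gamma", nBases = 30000, seed = 74,
                        shape = 0.5, scale = 4)
  h <- countHistogram(sim$counts)
  N <- totalBases(h)
  # the empirical pmf as the model gives zero error everywhere
  empPmf <- function(k) {
    idx <- match(k, histLevels(h))
    out <- histCounts(h)[idx] / N
    out[is.na(out)] <- 0
    out
  }
  p0 <- logLikError(h, empPmf)
  expect_equal(unname(errorByLevel(p0)), rep(0, length(histLevels(h))),
               tolerance = 1e-12)
  expect_equal(meanLogLikError(p0), 0, tolerance = 1e-12)

  # a model assigning zero mass to an observed level reports +Inf
  pz <- logLikError(h, function(k) ifelse(k >= 2, 0, dpois(k, 1)))
  expect_true(any(is.infinite(errorByLevel(pz))))

  # a Poisson fit underestimates the overdispersed tail: errors grow with k
  pp <- logLikError(h, fitPoisson(h))
  e <- errorByLevel(pp)
  top <- tail(e[is.finite(e)], 5)
  expect_true(all(diff(top) > 0))
  expect_gt(meanLogLikError(pp), 0)

  # nesting chain of mean errors: more flexible model, smaller error
  expect_gt(meanLogLikError(pp),
            meanLogLikError(logLikError(h, fitNegbin(h))))
})

test_that("diagnostics reports cover all families and serialize", {
  td <- withr::local_tempdir()
  sim <- simulateCounts("gamma", nBases = 20000, seed = 75,
                        shape = 2, scale = 0.5)
  h <- countHistogram(sim$counts)
  rep <- overdispersionDiagnostics(h, K = 256L, restarts = 3L)
  expect_setequal(names(rep$fits),
                  c("poisson", "dedup_poisson", "negbin",
                    "lognormal_poisson", "logconcave"))
  expect_gt(rep$meanErrors[["poisson"]], rep$meanErrors[["negbin"]])
  paths <- writeDiagnostics(rep, tsvPath = file.path(td, "d.tsv"),
                            jsonPath = file.path(td, "d.json"))
  tab <- read.delim(paths$tsv)
  expect_setequal(unique(tab$model), names(rep$fits))
  js <- jsonlite::fromJSON(file.path(td, "d.json"))
  expect_true(all(c("logLik", "meanError") %in% names(js$poisson)))
})
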