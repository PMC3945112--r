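test_that("latent grid span covers the data range under the default policy", {
  h <- countHistogram(c(rep(1, 5), 10), totalBases = 100)
  g <- makeLatentGrid(h, K = 64L)
  expect_gte(g@hi, log(10) + 2)
  expect_lte(g@lo, log(1 / 100))
  x <- gridPoints(g)
  expect_equal(length(x), 64L)
  expect_equal(diff(x), rep(gridStep(g), 63L), tolerance = 1e-12)
  g3 <- makeLatentGrid(h, K = 3L)
  expect_equal(gridPoints(g3), c(g3@lo, (g3@lo + g3@hi) / 2, g3@hi))
  expect_error(makeLatentGrid(h, K = 2L), "K >= 3")
})

test_that("Poisson kernel matches the pmf and rows sum to one", {
  h <- CountHistogram(level = c(0L, 2L), count = c(1, 1), nBases = 2)
  grid <- new("LatentGrid", lo = 0, hi = log(2), K = 3L)
  P <- poissonKernel(h, grid)
  expect_equal(unname(P[1, 1]), exp(-1), tolerance = 1e-12)     # k=0, rate 1
  expect_equal(unname(P[2, 3]), 2 * exp(-2), tolerance = 1e-12) # k=2, rate 2
  # column sums over all k up to a generous truncation reach 1
  full <- poissonKernel(h, grid, levels = 0:60)
  expect_equal(unname(colSums(full)), rep(1, 3), tolerance = 1e-12)
})

test_that("marginal log-likelihood: degenerate mixture, shift invariance, naive oracle", {
  # near-degenerate mass at log 2 -> Poisson(2) log-likelihood
  grid <- new("LatentGrid", lo = log(2) - 1, hi = log(2) + 1, K = 3L)
  h <- CountHistogram(level = 0L, count = 1, nBases = 1)
  g <- c(-1e8, 0, -1e8)
  expect_equal(marginalLogLik(g, grid, h), dpois(0, 2, log = TRUE),
               tolerance = 1e-9)

  set.seed(4)
  h2 <- poisHist(n = 500, rate = 3, seed = 4)
  grid2 <- makeLatentGrid(h2, K = 25L)
  g2 <- rnorm(25)
  expect_equal(marginalLogLik(g2, grid2, h2),
               marginalLogLik(g2 + 7, grid2, h2), tolerance = 1e-10)
  expect_equal(marginalLogLik(g2, grid2, h2),
               naiveMarginalLogLik(g2, grid2, h2), tolerance = 1e-10)
  expect_error(marginalLogLik(c(g2[-1], Inf), grid2, h2), "finite")
})

test_that("gradient components sum to zero and match central differences", {
  set.seed(5)
  for (rep in 1:5) {
    h <- poisHist(n = 300, rate = sample(1:4, 1), seed = 50 + rep)
    grid <- makeLatentGrid(h, K = 20L)
    g <- rnorm(20)
    an <- logLikGradient(g, grid, h)
    expect_lt(abs(sum(an)), 1e-8)
    fd <- vapply(1:20, function(j) {
      e <- rep(0, 20); e[j] <- 1e-6
      (marginalLogLik(g + e, grid, h) -
         marginalLogLik(g - e, grid, h)) / 2e-6
    }, numeric(1))
    # relative to the gradient scale; tiny components are dominated by
    # finite-difference cancellation noise
    expect_lt(max(abs(an - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("the likelihood is concave over mixture weights", {
  # the marginal likelihood is concave in the latent weights w on the
  # simplex (the mixture probabilities are linear in w); this is the
  # property that makes the maximum unique. In the log-density
  # coordinates g = log w used by the optimizer the surface is not
  # concave, which is why the fitter relies on monotone line searches.
  set.seed(6)
  h <- poisHist(n = 400, rate = 2, seed = 6)
  grid <- makeLatentGrid(h, K = 15L)
  ll <- function(w) marginalLogLik(log(w), grid, h)
  for (rep in 1:20) {
    w1 <- rgamma(15, 1); w1 <- w1 / sum(w1)
    w2 <- rgamma(15, 1); w2 <- w2 / sum(w2)
    t <- runif(1)
    mid <- ll(t * w1 + (1 - t) * w2)
    chord <- t * ll(w1) + (1 - t) * ll(w2)
    expect_gte(mid, chord - 1e-8)
  }
})

test_that("fitting recovers a concentrated latent for Poisson data", {
  h <- poisHist(n = 20000, rate = 2, seed = 11)
  fit <- fitLogConcave(h, K = 512L)
  expect_true(converged(fit))
  d <- latentDensity(fit)
  q <- latentQuantile(d, c(0.1, 0.9))
  expect_lt(max(abs(q - log(2))), 0.5)
  # density invariants
  g <- latentLogDensity(d)
  expect_lte(max(diff(g, differences = 2)), 1e-8)
  expect_equal(max(g), 0)
  w <- exp(g - d@logZ) * gridStep(latentGrid(d))
  expect_equal(sum(w), 1, tolerance = 1e-10)
  # best-iterate trace is non-decreasing
  expect_true(all(diff(logLikTrace(fit)) >= -1e-9))
})

test_that("an all-zero histogram pushes latent mass to the low-rate boundary", {
  # the grid's low edge sits at rate 0.5/N, so P(0) can approach
  # exp(-0.5/N); use enough bases for the bound to be meaningful
  h <- CountHistogram(level = 0L, count = 5000, nBases = 5000)
  fit <- fitLogConcave(h, K = 256L)
  expect_gte(marginalPmf(latentDensity(fit), 0), 1 - 1e-3)
  expect_lt(targetRate(latentDensity(fit)), 0.01)
})

test_that("fits are deterministic and beat the parametric fit they nest", {
  sim <- simulateCounts("gamma", nBases = 20000, seed = 21,
                        shape = 2, scale = 0.5)
  h <- countHistogram(sim$counts)
  f1 <- fitLogConcave(h, K = 512L)
  f2 <- fitLogConcave(h, K = 512L)
  expect_identical(latentLogDensity(latentDensity(f1)),
                   latentLogDensity(latentDensity(f2)))
  nb <- fitNegbin(h)
  expect_gte(logLik(f1), logLik(nb) - 1e-3 * totalBases(h))
})

test_that("marginal pmf is a probability distribution matching its simulation", {
  h <- poisHist(n = 20000, rate = 2, seed = 31)
  d <- latentDensity(fitLogConcave(h, K = 512L))
  # degenerate check
  grid <- new("LatentGrid", lo = log(3) - 1, hi = log(3) + 1, K = 3L)
  dd <- new("LogConcaveDensity", grid = grid, g = c(-700, 0, -700),
            logZ = log(gridStep(grid)))
  expect_equal(marginalPmf(dd, 0:8), dpois(0:8, 3), tolerance = 1e-8)
  # sums to 1 within truncation
  kmax <- 20 + ceiling(10 * sqrt(20))
  expect_equal(sum(marginalPmf(d, 0:kmax)), 1, tolerance = 1e-6)
  expect_error(marginalPmf(d, -1), ">= 0")
  # matches empirical frequencies of a large simulation from itself
  sim <- simulateCounts("tabulated", nBases = 50000, seed = 32,
                        grid = latentGrid(d), g = latentLogDensity(d))
  emp <- countHistogram(sim$counts)
  for (k in 0:4) {
    pk <- marginalPmf(d, k)
    ck <- histCounts(emp)[match(k, histLevels(emp))]
    if (is.na(ck)) ck <- 0
    se <- sqrt(pk * (1 - pk) * 50000)
    expect_lt(abs(ck - 50000 * pk), 3 * se + 3)
  }
})
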