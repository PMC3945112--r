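test_that("degenerate simulation has Poisson moments and is reproducible", {
  sim <- simulateCounts("degenerate", nBases = 1e5, seed = 1,
                        lambda = log(2))
  v <- sum(baseValues(sim$counts)) / 1e5
  expect_lt(abs(v - 2), 3 * sqrt(2 / 1e5))
  sim2 <- simulateCounts("degenerate", nBases = 1e5, seed = 1,
                         lambda = log(2))
  expect_identical(baseValues(sim$counts), baseValues(sim2$counts))
  expect_identical(sim$trueRates, sim2$trueRates)
  expect_equal(as.character(GenomicRanges::seqnames(
    positionRanges(sim$counts))[1]), "chrSim")
})

test_that("gamma-latent counts show the negative binomial dispersion identity", {
  for (depth in c(1, 4)) {
    sim <- simulateCounts("gamma", nBases = 1e5, seed = 2, shape = 1,
                          scale = 3, depthFactor = depth)
    di <- dispersionIndex(sim$counts)
    expect_lt(abs(di - (1 + 3 * depth)), 0.25 * (1 + 3 * depth))
  }
  expect_error(simulateCounts("gamma", nBases = 10, shape = -1), "shape")
})

test_that("the dedup-degenerate generator matches its binomial/uniform design", {
  pbc <- simulateDedupDegenerate(pNonzero = 0.1, maxCount = 5,
                                 nBases = 1e5, seed = 3)
  v <- baseValues(pbc)
  expect_lt(abs(length(v) / 1e5 - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
  tab <- tabulate(v, nbins = 5)
  expect_true(all(abs(tab / length(v) - 0.2) <
                    3 * sqrt(0.2 * 0.8 / length(v))))
  b <- simulateDedupDegenerate(0.3, 1, 1000, seed = 4)
  expect_true(all(baseValues(b) == 1))
  expect_error(simulateDedupDegenerate(1.5, 5, 10), "pNonzero")
})

test_that("dispersion index is calibrated and guards its domain", {
  set.seed(5)
  x <- rpois(1e5, 2)
  expect_true(dispersionIndex(x) > 0.97 && dispersionIndex(x) < 1.03)
  expect_equal(dispersionIndex(rep(3, 100)), 0)
  expect_error(dispersionIndex(rep(0, 10)), "zero mean")
  pbc <- PerBaseCounts("c", 0, 4, totalBases = 2)
  expect_equal(dispersionIndex(pbc), var(c(4, 0)) / 2)
})
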