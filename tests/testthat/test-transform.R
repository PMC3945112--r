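# continuous Poisson extensions and the Poissonization transform

test_that("continuous Poisson CDF extends the discrete one", {
  expect_equal(pcpois(0, 1), exp(-1), tolerance = 1e-12)
  expect_equal(pcpois(1, 1), 2 * exp(-1), tolerance = 1e-12)
  for (mu in c(0.5, 2, 10)) {
    expect_equal(pcpois(0:15, mu), ppois(0:15, mu), tolerance = 1e-12)
    for (x in c(0.5, 1, 3.7))
      expect_equal(qcpois(pcpois(x, mu), mu), x, tolerance = 1e-8)
  }
  expect_equal(dcpois(2, 3), dpois(2, 3), tolerance = 1e-12)
  expect_error(qcpois(1.2, 1), "in \\(0, 1\\)")
  expect_error(qcpois(0, 1), "in \\(0, 1\\)")
  expect_error(pcpois(1, -2), "> 0")
})

test_that("compound CDF reduces to Poisson for a degenerate latent and is monotone", {
  grid <- new("LatentGrid", lo = log(2) - 1, hi = log(2) + 1, K = 3L)
  dd <- new("LogConcaveDensity", grid = grid, g = c(-700, 0, -700),
            logZ = log(gridStep(grid)))
  xs <- c(0, 0.5, 1, 2, 5.3, 9)
  expect_equal(pcompound(xs, dd), pcpois(xs, 2), tolerance = 1e-9)

  h <- poisHist(n = 10000, rate = 2, seed = 41)
  d <- latentDensity(fitLogConcave(h, K = 512L))
  expect_lt(pcompound(1, d), pcompound(2, d))
  # matches the empirical CDF of its own simulation at integer points
  sim <- simulateCounts("tabulated", nBases = 50000, seed = 42,
                        grid = latentGrid(d), g = latentLogDensity(d))
  v <- baseValues(sim$counts)
  for (k in 0:3) {
    Fk <- pcompound(k, d)
    emp <- (50000 - sum(v > k)) / 50000
    expect_lt(abs(Fk - emp), 3 * sqrt(Fk * (1 - Fk) / 50000) + 1e-4)
  }
})

test_that("the target rate is the median of the latent rate distribution", {
  grid <- new("LatentGrid", lo = log(2) - 1, hi = log(2) + 1, K = 3L)
  dd <- new("LogConcaveDensity", grid = grid, g = c(-700, 0, -700),
            logZ = log(gridStep(grid)))
  expect_equal(targetRate(dd), 2, tolerance = 1e-6)
  # symmetric density about the grid midpoint -> median at the midpoint
  grid2 <- new("LatentGrid", lo = -1, hi = 3, K = 41L)
  x <- gridPoints(grid2)
  g <- -(x - 1)^2
  ds <- new("LogConcaveDensity", grid = grid2, g = g - max(g),
            logZ = logSumExp(g - max(g)) + log(gridStep(grid2)))
  expect_equal(targetRate(ds), exp(1), tolerance = 1e-9)
})

test_that("the transform is the identity for a matched Poisson model", {
  grid <- new("LatentGrid", lo = log(2) - 0.5, hi = log(2) + 0.5, K = 5L)
  g <- c(-1400, -700, 0, -700, -1400) # concave tent, mass at log 2 only
  dd <- new("LogConcaveDensity", grid = grid, g = g,
            logZ = log(gridStep(grid)))
  map <- buildTransform(dd, kMax = 20L)
  expect_equal(targetRate(map), 2, tolerance = 1e-6)
  tk <- adjustCount(0:20, map)
  expect_lt(max(abs(tk - 0:20)), 1e-3)
})

test_that("transform tables are strictly monotone and extend on demand", {
  sim <- simulateCounts("gamma", nBases = 20000, seed = 51,
                        shape = 0.5, scale = 4)
  h <- countHistogram(sim$counts)
  d <- latentDensity(fitLogConcave(h, K = 512L))
  map <- buildTransform(d, kMax = 10L)
  tk <- adjustCount(0:10, map)
  expect_true(all(diff(tk) > 0))
  expect_true(all(tk >= 0))
  # beyond the precomputed range the table extends consistently
  t25 <- adjustCount(25, map)
  big <- buildTransform(d, kMax = 30L)
  expect_equal(t25, adjustCount(25, big), tolerance = 1e-9)
  # heavy overdispersion compresses the tail
  expect_lt(adjustCount(10, map) - adjustCount(1, map), 9)
})

test_that("applyTransform is positionwise, rank-preserving and type-checked", {
  sim <- simulateCounts("gamma", nBases = 5000, seed = 52,
                        shape = 0.5, scale = 4)
  h <- countHistogram(sim$counts)
  map <- buildTransform(latentDensity(fitLogConcave(h, K = 256L)))
  adj <- applyTransform(sim$counts, map)
  raw <- baseValues(sim$counts)
  out <- baseValues(adj)
  expect_equal(length(out), length(raw))
  expect_equal(totalBases(adj), totalBases(sim$counts))
  # equal raw counts get equal adjusted values; rank order is preserved
  expect_equal(length(unique(out[raw == 2])), 1L)
  expect_equal(cor(raw, out, method = "spearman"), 1)
  expect_identical(GenomicRanges::start(positionRanges(adj)),
                   GenomicRanges::start(positionRanges(sim$counts)))
  expect_error(applyTransform(adj, map), "raw integer")

  # randomized PIT variant: seeded, within the deterministic bracket
  r1 <- applyTransform(sim$counts, map, randomized = TRUE, seed = 3)
  r2 <- applyTransform(sim$counts, map, randomized = TRUE, seed = 3)
  expect_identical(baseValues(r1), baseValues(r2))
  hi <- adjustCount(raw, map)
  lo <- ifelse(raw == 0, 0, adjustCount(pmax(raw - 1, 0), map))
  expect_true(all(baseValues(r1) <= hi + 1e-8 &
                    baseValues(r1) >= lo - 1e-8))
})
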