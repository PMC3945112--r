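test_that("flooring truncates and leaves integers alone", {
  expect_equal(floorRound(c(2.7, 0.999, 3)), c(2, 0, 3))
  expect_error(floorRound(-0.1), ">= 0")
})

test_that("randomized rounding is unbiased with support on the two neighbors", {
  t <- rep(2.3, 10000)
  r <- randomizedRound(t, seed = 1)
  expect_true(all(r %in% c(2, 3)))
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(r) - 2.3), 3 * se)
  expect_equal(randomizedRound(c(0, 2, 5), seed = 2), c(0, 2, 5))
  # sandwich property pointwise
  set.seed(3)
  t2 <- runif(500, 0, 6)
  r2 <- randomizedRound(t2, seed = 4)
  expect_true(all(r2 >= floorRound(t2) & r2 <= floorRound(t2) + 1))
})

test_that("replicate generation is seeded, unbiased and scheme-checked", {
  v <- c(0.2, 1.7, 2.5, 3.9, 0.01)
  pbc <- PerBaseCounts(rep("chrSim", 5), 0:4, v, totalBases = 10)
  r1 <- generateReplicates(pbc, replicates = 2, seed = 99)
  r2 <- generateReplicates(pbc, replicates = 2, seed = 99)
  expect_identical(lapply(r1, baseValues), lapply(r2, baseValues))
  # replicate r does not depend on how many replicates are requested
  r5 <- generateReplicates(pbc, replicates = 5, seed = 99)
  expect_identical(baseValues(r1[[2]]), baseValues(r5[[2]]))

  reps <- generateReplicates(pbc, replicates = 30, seed = 7)
  means <- rowMeans(vapply(reps, baseValues, numeric(5)))
  se <- sqrt(pmax(v - floor(v), 1e-9) * (1 - pmin(v - floor(v), 1)) / 30)
  expect_true(all(abs(means - v) <= 3 * se + 1e-9))

  fl <- generateReplicates(pbc, replicates = 1, scheme = "floor")
  expect_length(fl, 1L)
  expect_equal(baseValues(fl[[1]]), floor(v))
  expect_error(generateReplicates(pbc, replicates = 2, scheme = "floor"),
               "deterministic")
})

test_that("floored adjusted counts take few distinct values on overdispersed data", {
  sim <- simulateCounts("gamma", nBases = 50000, seed = 61,
                        shape = 0.4, scale = 10)
  h <- countHistogram(sim$counts)
  map <- buildTransform(latentDensity(fitLogConcave(h, K = 512L)))
  raw <- 1:20
  fl <- floorRound(adjustCount(raw, map))
  expect_lte(length(unique(fl)), 4L)
  expect_true(all(diff(fl) >= 0)) # monotone in the raw count
})
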