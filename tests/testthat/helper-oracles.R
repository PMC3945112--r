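# independent oracles used across tests; deliberately naive so they stay
# independent of the implementation paths they check

# direct double-loop marginal log-likelihood with explicit normalization
naiveMarginalLogLik <- function(g, grid, hist) {
  x <- gridPoints(grid)
  w <- exp(g) / sum(exp(g))
  lev <- histLevels(hist)
  total <- 0
  for (i in seq_along(lev)) {
    p <- 0
    for (j in seq_along(x)) p <- p + w[j] * dpois(lev[i], exp(x[j]))
    total <- total + histCounts(hist)[i] * log(p)
  }
  total
}

# concave projection through a generic quadratic program (test-only)
qpConcaveProject <- function(v, weights = rep(1, length(v))) {
  n <- length(v)
  D <- matrix(0, n - 2, n)
  for (j in seq_len(n - 2)) D[j, j:(j + 2)] <- c(1, -2, 1)
  res <- pracma::quadprog(diag(weights), -weights * v, A = D,
                          b = rep(0, n - 2))
  res$xmin
}

# small deterministic Poisson histogram fixture
poisHist <- function(n = 5000, rate = 2, seed = 1) {
  set.seed(seed)
  countHistogram(rpois(n, rate), totalBases = n)
}

# chi-square goodness of fit of integer counts against Poisson with the
# counts' own mean; bins pooled to expected >= 5, df = bins - 2
poissonGofPvalue <- function(values, nBases) {
  m <- sum(values) / nBases
  kmax <- max(values)
  obs <- c(nBases - length(values),
           tabulate(factor(values[values > 0], levels = 1:kmax)))
  p <- dpois(0:kmax, m)
  p[kmax + 1] <- p[kmax + 1] + ppois(kmax, m, lower.tail = FALSE)
  expc <- nBases * p
  k <- length(obs)
  while (k > 2 && expc[k] < 5) {
    expc[k - 1] <- expc[k - 1] + expc[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    expc <- expc[-k]; obs <- obs[-k]
    k <- k - 1
  }
  X2 <- sum((obs - expc)^2 / expc)
  pchisq(X2, df = max(length(obs) - 2, 1), lower.tail = FALSE)
}
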