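#' Fit a latent log-concave distribution to a count histogram
#'
#' Maximum-likelihood inference of the nonparametric latent distribution
#' over Poisson log-rates: the marginal likelihood is maximized over
#' concave log-density vectors `g` on the quadrature grid by accelerated
#' (Nesterov) proximal gradient ascent, where the proximal step is the
#' Euclidean projection onto concave sequences ([projectConcave()]). The
#' likelihood is concave in the latent mixture weights, which makes the
#' maximum essentially unique; in the log-density coordinates the ascent
#' operates in, the surface is not globally concave, so convergence is
#' enforced by monotone line searches and the reached fit is
#' cross-checked in the test suite against the nested parametric optima
#' it must dominate.
#'
#' Numerical scheme: backtracking line search (step halving under the
#' standard proximal-gradient sufficient-increase condition), Nesterov
#' momentum with adaptive restart whenever the objective decreases,
#' interleaved over-relaxed fixed-point (EM-type) polish phases that
#' escape the flat ridges this likelihood is prone to, and an
#' identifiability pin `max(g) = 0` after every projection (the objective
#' is shift-invariant). The optimizer is fully deterministic: repeated
#' runs on the same inputs are bit-identical.
#'
#' @param hist a [CountHistogram-class] with `N >= 1`.
#' @param grid a [LatentGrid-class]; built by [makeLatentGrid()] with `K`
#'   points when omitted.
#' @param K grid size used when `grid` is not supplied.
#' @param maxIter iteration cap; non-convergence is reported via the
#'   `converged` flag, not an error.
#' @param tol relative-objective stopping tolerance (met on 5 consecutive
#'   iterations), with `maxAbs(g change) < 1e-8` as an alternative stop.
#' @param verbose print objective every 50 iterations.
#' @param coarseInit for large grids, first solve on a K/8 grid with the
#'   same span and refine from the interpolated solution (identical
#'   optimum, substantially fewer fine-grid iterations).
#' @param patience stop when the best objective has not improved by a
#'   relative `tol` within this many iterations. Fixed-point (EM-style)
#'   polish steps are interleaved whenever the gradient ascent stalls,
#'   which escapes the flat ridges this likelihood is prone to.
#' @return a [LogConcaveFit-class].
#' @examples
#' h <- countHistogram(rpois(5000, 2), totalBases = 5000)
#' fit <- fitLogConcave(h, K = 256L)
#' targetRate(latentDensity(fit))
#' @export
fitLogConcave <- function(hist, grid = NULL, K = 4096L, maxIter = 5000L,
                          tol = 1e-9, verbose = FALSE, coarseInit = TRUE,
                          patience = 50L) {
  stopifnot2(is(hist, "CountHistogram"), "'hist' must be a CountHistogram")
  stopifnot2(hist@nBases >= 1, "histogram must cover at least one base")
  if (is.null(grid)) grid <- makeLatentGrid(hist, K = K)
  x <- gridPoints(grid)
  N <- hist@nBases
  logKernel <- poissonKernel(hist, grid, log = TRUE)
  obj <- function(g) marginalLogLik(g, grid, hist, logKernel) / N
  grad <- function(g) logLikGradient(g, grid, hist, logKernel) / N

  if (coarseInit && grid@K >= 2048L) {
    # coarse-to-fine: solve on a K/8 grid with the same span first (cheap
    # per iteration), then refine; linear interpolation preserves
    # concavity on a uniform grid
    coarse <- new("LatentGrid", lo = grid@lo, hi = grid@hi,
                  K = as.integer(max(ceiling(grid@K / 8), 512L)))
    cf <- fitLogConcave(hist, grid = coarse, maxIter = maxIter, tol = tol,
                        verbose = verbose, coarseInit = FALSE,
                        patience = patience)
    g <- stats::approx(gridPoints(coarse), cf@density@g, xout = x,
                       rule = 2)$y
    g <- g - max(g)
  } else {
    # concave (quadratic) initialization: a moment-matched log-normal
    # latent. For a log-normal latent with parameters (m_ln, s_ln) the
    # marginal mean is m and the excess dispersion is (s2 - m)/m^2 =
    # exp(s_ln^2) - 1, so equidispersed data start almost at a point mass
    # and overdispersed data start near the right spread.
    meanRate <- max(sum(hist@level * hist@count) / N, 0.5 / N)
    s2 <- sum(hist@count * (hist@level - meanRate)^2) / max(N - 1, 1)
    sig2 <- log1p(max((s2 - meanRate) / meanRate^2, 1e-4))
    g <- -(x - (log(meanRate) - sig2 / 2))^2 / (2 * sig2)
    g <- g - max(g)
  }

  mu <- numeric(0) # warm-started projection duals
  ones <- rep(1, length(x))
  # log-density values below max(g) - 800 are numerically zero density;
  # flooring them there bounds the dual scale of the projection, which is
  # what limits the attainable concavity precision
  prox <- function(v, quality = 1e-6) {
    v <- pmax(v, max(v) - 800)
    scale <- max(1, max(abs(v)))
    res <- .concaveProjectCpp(v, ones, 1e-10 * scale, 0L, mu)
    mu <<- res$mu
    if (res$maxViolation > quality * scale) return(NULL)
    res$u - max(res$u)
  }

  g <- prox(g)
  fg <- obj(g)
  y <- g
  theta <- 1
  step <- 1
  best <- g; fbest <- fg
  trace <- numeric(maxIter)
  flat <- 0L
  it <- 0L
  lastGain <- 0L
  convergedFlag <- FALSE

  # fixed-point (EM-style) polish: replace the latent weights by the
  # posterior-aggregated weights and re-project, with over-relaxation
  # along the fixed-point direction (alpha > 1, the classical EM
  # accelerator) because plain EM crawls on the flat ridges of this
  # likelihood. A step is only adopted when it improves the objective,
  # so monotonicity of the best iterate is preserved.
  emPolish <- function(g0, f0) {
    gcur <- g0; fcur <- f0; improved <- FALSE
    for (e in seq_len(100L)) {
      M <- logKernel + rep(gcur, each = nrow(logKernel))
      post <- exp(M - rowLogSumExp(M))
      wpost <- as.numeric(crossprod(post, hist@count)) / N
      dirn <- log(pmax(wpost, 1e-300)) - gcur
      fstep <- -Inf; gstep <- NULL
      for (alpha in c(1, 2, 4, 8)) {
        cand <- prox(gcur + alpha * dirn, quality = Inf)
        fcand <- obj(cand)
        if (fcand > fstep) { fstep <- fcand; gstep <- cand }
        if (alpha > 1 && fcand < fstep) break
      }
      if (fstep > fcur + max(tol * abs(fcur), 0.05 / N)) {
        gcur <- gstep; fcur <- fstep; improved <- TRUE
      } else break
    }
    if (improved) list(g = gcur, f = fcur) else NULL
  }

  # cycles of accelerated proximal-gradient ascent followed by an
  # EM-style polish phase; a cycle that gains less than 1 nat in total
  # log-likelihood ends the optimization
  while (it < maxIter && !convergedFlag) {
    fCycle <- fbest
    inner <- 0L
    while (it < maxIter && inner < patience) {
      it <- it + 1L; inner <- inner + 1L
      gy <- grad(y)
      fy <- obj(y)
      step <- min(step * 1.25, 1e5)
      repeat {
        gNew <- prox(y + step * gy)
        ok <- !is.null(gNew)
        if (ok) {
          d <- gNew - y
          fNew <- obj(gNew)
          ok <- fNew >= fy + sum(gy * d) - sum(d * d) / (2 * step) - 1e-13
        }
        if (ok) break
        step <- step / 2
        if (step < 1e-14) { gNew <- y; fNew <- fy; break }
      }
      thetaNew <- (1 + sqrt(1 + 4 * theta^2)) / 2
      if (fNew < fg) { # adaptive restart: drop momentum
        y <- gNew
        thetaNew <- 1
      } else {
        y <- gNew + ((theta - 1) / thetaNew) * (gNew - g)
      }
      dg <- max(abs(gNew - g))
      rel <- abs(fNew - fg) / (abs(fg) + 1e-12)
      g <- gNew; fg <- fNew
      theta <- thetaNew
      if (fg > fbest) { fbest <- fg; best <- g }
      trace[it] <- fbest * N
      if (verbose && it %% 50L == 0L)
        message(sprintf("iter %5d  logLik %.8g  step %.3g", it, fbest * N,
                        step))
      flat <- if (rel < tol) flat + 1L else 0L
      if (flat >= 5L || dg < 1e-8) break
    }
    em <- emPolish(best, fbest)
    if (!is.null(em)) {
      g <- em$g; fg <- em$f; y <- g; theta <- 1
      best <- g; fbest <- fg
      if (it >= 1L) trace[it] <- fbest * N
    }
    if (fbest - fCycle < 0.5 / N) convergedFlag <- TRUE
  }

  mu <- numeric(0) # final clean projection from a cold start
  g <- prox(best, quality = Inf)
  if (max(diff(g, differences = 2)) > 1e-10) {
    # polish: the iterate is already near-concave, so a second cold
    # projection has tiny dual multipliers and machine-precision output
    g <- prox(g, quality = Inf)
  }
  density <- new("LogConcaveDensity", grid = grid, g = g,
                 logZ = logSumExp(g) + log(gridStep(grid)))
  new("LogConcaveFit", density = density, logLikTrace = trace[seq_len(it)],
      logLik = marginalLogLik(g, grid, hist, logKernel),
      converged = convergedFlag, nIter = it)
}
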