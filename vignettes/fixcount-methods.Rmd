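---
title: "Poisson calibration of overdispersed per-base counts: model and methods"
author: "fixcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson calibration of overdispersed per-base counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixcount)
```

## The problem

Many sequencing analysis tools — peak callers, footprint callers, exon
counters — assume, implicitly or explicitly, that per-base read counts are
Poisson around a local mean. Real ChIP-seq, DNase-seq and RNA-seq data are
strongly overdispersed at the single-base level: the variance of counts
exceeds the mean several-fold, the tail of the count histogram is far
heavier than exponential, and no single two-parameter family (negative
binomial, log-normal-Poisson) fits all assay types. Tools built on the
Poisson assumption then mis-state significance, and the popular remedy —
de-duplication, keeping one read per base — throws information away and
degrades as depth grows.

fixcount treats this as a calibration problem. It models counts as a
compound Poisson process whose per-base log-rates are drawn from an
unknown *log-concave* distribution, fits that latent distribution to the
count histogram by maximum likelihood, and then maps each observed count
through the fitted distribution's continuous CDF and back through a
continuous Poisson inverse CDF. Downstream tools see counts whose
distribution is as close to Poisson as the data allow, while every base
keeps its rank and its position.

## The model

Counts $n_i$ at base $i$ are generated as

$$\lambda_i \sim f, \qquad n_i \mid \lambda_i \sim
  \mathrm{Poisson}(e^{\lambda_i}),$$

where $f$ is a density on the log-rate axis with $\log f$ concave.
Log-concavity buys a flexible yet estimable nonparametric family: it
contains the degenerate (pure Poisson), gamma and log-normal latents as
special cases, enforces unimodality, and ties the unidentified tails of
the latent distribution to its well-identified body.

The latent axis is discretized on a uniform grid $x_1 < \dots < x_K$
(midpoint quadrature). With $c_k$ the number of bases carrying exactly
$k$ reads and $P_{kj} = \mathrm{Pois}(k \mid e^{x_j})$, the marginal
log-likelihood of the histogram under log-density values $g_j$ is

$$L(g) = \sum_k c_k \log \sum_j P_{kj}\, e^{g_j}
         \;-\; N \log \sum_j e^{g_j},$$

with quadrature weights cancelling between the mixture and its
normalizer. Fitting cost therefore depends on the number of *distinct*
count levels, not on genome size: a whole-genome dataset reduces to a
histogram with a few dozen rows.

One point deserves honesty: $L$ is concave in the mixture *weights*
$w_j = e^{g_j}$ on the simplex — which is what makes the maximum
essentially unique — but it is **not** concave in the log-space
coordinates $g$ the optimizer works in (a chord test falsifies this
directly, and the package's test suite contains that counterexample).
Convergence is therefore enforced by monotone line searches rather than
claimed from convexity, and every fit used in the test suite is
cross-checked against the parametric optima it must dominate: a gamma
latent is log-concave, so the fitted log-likelihood has to reach the
negative binomial MLE's, up to quadrature and stopping error.

## The fitting algorithm

Maximization alternates two deterministic engines:

1. **Accelerated proximal gradient ascent.** The gradient has the
   interpretable form *posterior minus prior* grid mass; the proximal
   step is the Euclidean projection onto the cone of concave sequences
   (second differences $\le 0$) — classical concave regression. Steps use
   backtracking line search with Nesterov momentum and adaptive restart,
   and the identifiability pin $\max_j g_j = 0$ after every projection.
2. **Over-relaxed fixed-point (EM-type) polish.** The likelihood has
   long flat ridges (reshaping the latent tail moves it by fractions of
   a nat); when gradient ascent stalls, the fitter takes steps along the
   fixed-point direction $g \mapsto \log(\text{posterior mass})$ with
   over-relaxation factors $\{1, 2, 4, 8\}$, projected back onto the
   cone, adopting a step only when it improves the objective.

Fitting runs in cycles of 50 gradient iterations plus one polish phase
and stops when a complete cycle improves the total log-likelihood by
less than 0.5 nat — a stopping scale chosen because it is far below the
sampling noise of any quantity the transform consumes. For large grids
the fit first solves a $K/8$ grid with the same span and refines
(linear interpolation preserves concavity on a uniform grid). The whole
procedure is deterministic: repeated fits are bit-identical.

The concave projection itself is solved exactly in compiled code through
the dual nonnegative least-squares problem, whose normal matrix is
pentadiagonal: block principal pivoting with banded Cholesky solves,
falling back to a warm-started Lawson–Hanson iteration (monotone,
cycle-free) on adversarial inputs. Agreement with a generic
quadratic-programming solver is part of the test suite. On inputs whose
dual multipliers are astronomically large (e.g. projecting a long random
walk), attainable feasibility is limited by floating-point cancellation
to a few $10^{-13}$ times the multiplier scale; the projector reports
its realized feasibility, and fitted densities satisfy second
differences $\le 10^{-8}$.

## Tunable parameters

* `K` (quadrature points, default 4096). The objective depends on the
  grid only through quadrature error; 4096 points over the default span
  give steps of ~0.004 on the log-rate axis, far finer than any feature
  the data can resolve. The grid span runs from $\log(0.5/N)$ — "half an
  expected read in the whole dataset" — to $\log(\max_k k) + 3$.
* `targetRate` ($\mu$, default: median of the fitted latent rate
  distribution). The Poissonization map has one free parameter, the rate
  of the reference Poisson; any fixed choice yields an equivalent
  monotone map, and the latent median makes adjusted counts commensurate
  with raw ones. An explicit override supports matched-rate cross-sample
  work.
* Rounding: `floorRound` (deterministic; a generalization of
  de-duplication) and `randomizedRound` (unbiased; rounds up with
  probability equal to the fractional part). `generateReplicates`
  defaults to 30 replicates — the point at which downstream aggregate
  performance saturates — with one deterministic substream per replicate.

## The transform and its conventions

The map is $t_k = F_{\mathrm{Pois}}^{-1}(F(k); \mu)$ with $F$ the fitted
compound distribution's continuous CDF (a mixture of continuous-Poisson
CDFs $Q(x+1, e^{x_j})$, the regularized upper incomplete gamma) and the
inverse taken on the *log-survival* scale, so tail counts transform
without saturation. The package evaluates the CDF at the integer count
itself and uses the deterministic $u = F(k)$ rather than the randomized
$u \sim U[F(k-1), F(k)]$: determinism, reproducibility and exact rank
preservation outweigh the randomized variant's closer distributional
match in the continuum (and at small $\mu$ the randomized variant is
*worse* after rounding, because it smears each atom across a wide
interval). Equal raw counts always receive equal adjusted values; the
map is strictly increasing and extends its lookup table on demand.

Because the raw counts are discrete, no transform of this family makes
the *rounded* adjusted counts exactly Poisson: each atom $c_k$ lands on
one adjusted value, and rounding splits it between two integers. The
residual is invisible to dispersion-style statistics (adjusted
dispersion indexes land at $1.0$–$1.1$ where raw data sit at $5$) but is
detectable by a chi-square goodness-of-fit test once $n \gtrsim 2\times
10^4$ bases: at $n = 10^5$ the construction leaves a chi-square mass of
a few hundred. Users should read the transform as removing
overdispersion, not as producing literally Poisson samples.

## The synthetic-data generator

`simulateCounts()` draws per-base rates from degenerate, gamma,
log-normal or tabulated (grid) latents, scales them by a `depthFactor`
to emulate deeper sequencing of the same library, and draws Poisson
counts on a synthetic chromosome `chrSim`. `simulateDedupDegenerate()`
implements the degenerate model under which de-duplication is the exact
distribution-matching transform: bases are nonzero with a binomial
probability and nonzero levels are uniform. All generators are seeded
and return the true rates for recovery tests.

What the generator does *not* emulate: spatial correlation along the
genome (real enrichment is locally smooth; the model and the transform
are positionwise, so this does not affect their correctness, but tests
on synthetic data cannot probe window-level behaviour), mappability
holes, GC bias, or copy-number mixtures. Passing tests show that the
estimator and transform do what they claim under the stated compound
model — not that any particular real assay satisfies that model.

## Problem sizes and numerical choices in the test suite

Simulations in tests and in `scripts/acceptance.R` use $10^5$ bases
(histograms of 14–130 levels), $K = 4096$ for headline fits and
$K = 1024$ for the five-fit depth sweep, where the per-base error metric
is grid-insensitive. Root-finding tolerances are $10^{-10}$; kernel
truncation for pmf normalization uses $k_{\max} = \max_k k + 10
\sqrt{\max_k k}$.

Two phenomena observed at these sizes are worth knowing about:

* **The identity case tracks sampling noise.** On pure Poisson data the
  fitted latent width follows the sample's dispersion draw (SE
  $\sqrt{2/n} \approx 0.0045$ at $n = 10^5$), and the induced deviation
  of the transform from the identity at count 10 is roughly $12
  \,|\widehat{\mathrm{disp}} - 1|$ — a few hundredths, with seed-to-seed
  variation of the same order. This is the maximum-likelihood estimate
  responding to the data, not an optimizer artifact: the likelihood
  genuinely prefers the wider latent on high-dispersion draws.
* **Latent recovery is limited by identifiability at low rates.** Rates
  far below one read per base produce only zeros; a gamma(0.5) latent
  has ~8% of its mass in that region, and the fitted latent CDF can
  deviate by ~0.1 there while the *marginal count* distribution matches
  to sampling accuracy. Tests therefore assert the identified
  quantities — the marginal pmf against its own simulation, the latent
  median against the analytic gamma median — rather than a uniform
  latent-CDF bound.

## Worked example

```{r example, eval = FALSE}
sim <- simulateCounts("gamma", nBases = 1e5, seed = 1,
                      shape = 0.5, scale = 4)
dispersionIndex(sim$counts)            # ~5: strongly overdispersed
h   <- countHistogram(sim$counts)
fit <- fitLogConcave(h)
map <- buildTransform(latentDensity(fit))
adj <- applyTransform(sim$counts, map)
rounded <- generateReplicates(adj, replicates = 30, seed = 7)
dispersionIndex(rounded[[1]])          # ~1.1: Poisson-calibrated
```

## Known limitations

* Single latent distribution genome-wide; no per-chromosome or locally
  varying latents, no mixtures of log-concave components.
* No covariate correction (GC, mappability); fixcount composes with
  tools that do.
* The chi-square non-exactness of rounded adjusted counts described
  above.
* Multi-sample joint normalization is out of scope by design: with
  heavy count ties, rank-based quantile normalization would need
  arbitrary tie-breaking.
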