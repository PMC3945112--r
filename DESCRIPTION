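Package: fixcount
Title: Poisson Calibration of Overdispersed Per-Base Sequencing Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-base read counts from ChIP-seq, DNase-seq and RNA-seq
    experiments are strongly overdispersed relative to the Poisson
    distribution that many downstream callers assume. fixcount fits a
    nonparametric compound-Poisson model in which per-base log-rates are
    drawn from a log-concave latent distribution, estimated by accelerated
    proximal gradient ascent with projection onto concave sequences, and
    then maps observed counts through a continuous probability integral
    transform onto a Poisson reference so that Poisson-assuming tools see
    calibrated counts. Includes flooring and unbiased randomized rounding
    for integer-only consumers, parametric baseline fits (Poisson,
    negative binomial, log-normal-Poisson) with per-base log-likelihood
    error diagnostics, bedGraph/BED import and export, and a seeded
    compound-Poisson simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
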