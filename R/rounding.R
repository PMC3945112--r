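#' Integer rounding schemes for adjusted counts
#'
#' Downstream tools that only accept integral counts need the fractional
#' adjusted values rounded. `floorRound()` truncates (a deterministic
#' generalization of de-duplication: at typical depths it collapses low
#' adjusted counts onto one or two integer values). `randomizedRound()`
#' rounds up with probability equal to the fractional part, which is
#' unbiased: `E[output] = t` exactly, and the output is always `floor(t)`
#' or `floor(t) + 1`.
#'
#' @param t non-negative numeric values (adjusted counts).
#' @param seed optional integer seed making the draw reproducible.
#' @return integer-valued numeric vector of the same length.
#' @examples
#' floorRound(c(2.7, 0.999, 3))
#' mean(randomizedRound(rep(2.3, 1e4), seed = 1)) # ~2.3
#' @export
floorRound <- function(t) {
  stopifnot2(all(t >= 0), "adjusted counts must be >= 0")
  floor(t)
}

#' @rdname floorRound
#' @export
randomizedRound <- function(t, seed = NULL) {
  stopifnot2(all(t >= 0), "adjusted counts must be >= 0")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  f <- floor(t)
  f + stats::rbinom(length(t), 1L, t - f)
}

#' Generate randomized-rounding replicate datasets
#'
#' Draws `replicates` independent randomized roundings of the adjusted
#' counts, each from its own deterministic substream derived from `seed`,
#' so replicate `r` is reproducible independently of how many replicates
#' are requested before it. Around thirty replicates are enough for
#' downstream aggregate performance to saturate, hence the default.
#'
#' @param counts a [PerBaseCounts-class] with (fractional) adjusted values.
#' @param replicates number of replicate datasets (`>= 1`).
#' @param seed master integer seed.
#' @param scheme `"randomized"` (default) or `"floor"`; flooring is
#'   deterministic, so requesting several floored replicates is an error.
#' @return a list of integer-valued [PerBaseCounts-class] objects.
#' @export
generateReplicates <- function(counts, replicates = 30L, seed = 1L,
                               scheme = c("randomized", "floor")) {
  scheme <- match.arg(scheme)
  stopifnot2(replicates >= 1, "replicates must be >= 1")
  if (scheme == "floor") {
    if (replicates > 1)
      stop("flooring is deterministic: use replicates = 1", call. = FALSE)
    gr <- counts@positions
    gr$score <- floorRound(baseValues(counts))
    return(list(new("PerBaseCounts", positions = gr,
                    totalBases = counts@totalBases)))
  }
  v <- baseValues(counts)
  lapply(seq_len(replicates), function(r) {
    gr <- counts@positions
    gr$score <- randomizedRound(v, seed = .substreamSeed(seed, r))
    new("PerBaseCounts", positions = gr, totalBases = counts@totalBases)
  })
}

# deterministic per-replicate seed, independent of how many replicates
# are drawn (a small splitmix-style integer hash, kept inside 2^31)
.substreamSeed <- function(seed, r) {
  x <- (as.numeric(seed) * 2654435761 + r * 40503) %% 2147483647
  as.integer(x)
}
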