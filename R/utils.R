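# numerically stable log(sum(exp(x))), optionally along matrix rows
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

rowLogSumExp <- function(M) {
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  bad <- !is.finite(m)
  out <- m + log(rowSums(exp(M - m)))
  out[bad] <- m[bad]
  out
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
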