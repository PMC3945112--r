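#' Read per-base counts from a bedGraph file
#'
#' Expands a 4-column bedGraph (0-based, half-open intervals) into per-base
#' records. Intervals must be non-overlapping within a chromosome and
#' values non-negative. Zero-valued intervals contribute to the covered
#' domain but are not stored as records.
#'
#' The size of the considered (mappable) domain matters for model fitting
#' because it fixes the number of zero-count bases \eqn{c_0}. By default it
#' is the sum of covered interval lengths; pass `genomeSize` or a
#' `chromSizes` file to state the true mappable-domain size explicitly.
#'
#' @param path bedGraph file (plain or gzip; track/comment lines ignored).
#' @param genomeSize explicit total domain size (overrides the default).
#' @param chromSizes optional path to a UCSC-style `chrom.sizes` file whose
#'   summed sizes define the domain.
#' @return a [PerBaseCounts-class].
#' @export
readBedGraph <- function(path, genomeSize = NULL, chromSizes = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e)
                   stop("failed to parse bedGraph '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (length(gr) > 0) {
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits) > 0) {
      i <- S4Vectors::queryHits(hits)[1L]
      j <- S4Vectors::subjectHits(hits)[1L]
      stop(sprintf("overlapping bedGraph intervals: records %d and %d (%s:%d-%d / %s:%d-%d)",
                   i, j,
                   as.character(GenomicRanges::seqnames(gr)[i]),
                   GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i],
                   as.character(GenomicRanges::seqnames(gr)[j]),
                   GenomicRanges::start(gr)[j] - 1L, GenomicRanges::end(gr)[j]),
           call. = FALSE)
    }
    if (any(gr$score < 0)) stop("negative values in bedGraph", call. = FALSE)
  }
  covered <- sum(as.numeric(GenomicRanges::width(gr)))
  total <- if (!is.null(genomeSize)) as.numeric(genomeSize)
           else if (!is.null(chromSizes)) sum(readChromSizes(chromSizes))
           else covered
  gr <- gr[gr$score > 0]
  w <- GenomicRanges::width(gr)
  chrom <- rep(as.character(GenomicRanges::seqnames(gr)), w)
  pos0 <- rep(GenomicRanges::start(gr) - 1L, w) + (sequence(w) - 1L)
  PerBaseCounts(chrom, pos0, rep(gr$score, w), totalBases = total)
}

#' Read per-base counts from mapped reads in BED format
#'
#' Each read contributes one count at its strand-aware 5' base (the start
#' for `+` reads, `end - 1` for `-` reads; unstranded reads are treated as
#' `+`), optionally shifted toward the 3' end, then counts are summed per
#' base across strands.
#'
#' @param path BED file of mapped reads.
#' @param shift integer shift applied in the 3' direction.
#' @param genomeSize optional explicit domain size; defaults to the number
#'   of distinct covered bases.
#' @return a [PerBaseCounts-class].
#' @export
readBedReads <- function(path, shift = 0L, genomeSize = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("failed to parse BED '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (length(gr) == 0) {
    return(PerBaseCounts(totalBases = if (is.null(genomeSize)) 0
                                      else as.numeric(genomeSize)))
  }
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  p5 <- ifelse(minus, GenomicRanges::end(gr), GenomicRanges::start(gr))
  p5 <- p5 + ifelse(minus, -shift, shift)
  key <- paste0(as.character(GenomicRanges::seqnames(gr)), "\r", p5)
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  pos1 <- as.integer(vapply(parts, `[[`, "", 2L))
  total <- if (is.null(genomeSize)) length(tab) else as.numeric(genomeSize)
  PerBaseCounts(chrom, pos1 - 1L, as.numeric(tab), totalBases = total)
}

#' Write per-base counts as bedGraph
#'
#' Adjacent bases with equal (rounded) values are merged into one interval;
#' zero-valued bases are omitted (sparse convention). Round-trips with
#' [readBedGraph()] up to `precision` decimal places.
#'
#' @param x a [PerBaseCounts-class].
#' @param path output file; a `.gz` suffix triggers gzip compression.
#' @param precision decimal places written for fractional values.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(x, path, precision = 4L) {
  gr <- x@positions
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))[ord]
  pos <- GenomicRanges::start(gr)[ord] - 1L # back to 0-based
  val <- round(as.numeric(gr$score)[ord], precision)
  keep <- val > 0
  chrom <- chrom[keep]; pos <- pos[keep]; val <- val[keep]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(val) == 0) return(invisible(path))
  newRun <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                    pos[-1] != pos[-length(pos)] + 1L |
                    val[-1] != val[-length(val)])
  runId <- cumsum(newRun)
  first <- which(newRun)
  len <- tabulate(runId)
  lines <- paste(chrom[first], pos[first], pos[first] + len,
                 vapply(val[first], format, "", trim = TRUE,
                        scientific = FALSE, digits = 15), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a chrom.sizes file
#' @param path two-column file: chromosome name, size.
#' @return named numeric vector of sizes.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "size"))
  stats::setNames(as.numeric(tab$size), tab$chrom)
}

#' @describeIn countHistogram tabulate a per-base dataset; `totalBases` is
#'   taken from the object.
#' @export
setMethod("countHistogram", "PerBaseCounts", function(x, ...) {
  countHistogram(baseValues(x), totalBases = totalBases(x))
})

#' @describeIn countHistogram tabulate a numeric vector of raw counts.
#' @param totalBases total number of bases including zero-count bases.
#' @export
setMethod("countHistogram", "numeric", function(x, totalBases = length(x)) {
  if (any(x != round(x)))
    stop("count histograms are defined on raw integer counts only",
         call. = FALSE)
  x <- as.integer(round(x))
  if (any(x < 0)) stop("counts must be >= 0", call. = FALSE)
  tab <- table(x[x > 0])
  CountHistogram(level = as.integer(names(tab)), count = as.numeric(tab),
                 nBases = totalBases)
})

#' Read / write a count histogram as two-column text
#'
#' The text format is one `level<TAB>count` pair per line (comments
#' starting with `#` are ignored on read). Because the histogram fully
#' determines the fit, this is the most compact way to ship a dataset.
#'
#' @param path histogram text file (plain or gzip).
#' @param nBases optional explicit total bases; defaults to the level-0
#'   entry being present in the file.
#' @return a [CountHistogram-class] (read) or `path` (write, invisibly).
#' @export
readCountHistogram <- function(path, nBases = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#",
                           col.names = c("level", "count"))
  CountHistogram(level = tab$level, count = tab$count,
                 nBases = if (is.null(nBases)) sum(tab$count)
                          else as.numeric(nBases))
}

#' @rdname readCountHistogram
#' @param hist a [CountHistogram-class].
#' @export
writeCountHistogram <- function(hist, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(hist@level, format(hist@count, trim = TRUE,
                                      scientific = FALSE), sep = "\t"), con)
  invisible(path)
}
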