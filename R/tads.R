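# Consensus TAD-boundary calling across many Hi-C samples: smoothed
# per-bin sample counts, then maximal runs of qualifying bins collapsed to
# midpoint boundary positions.

#' Count boundary-supporting samples per genomic bin
#'
#' Segments each chromosome into \code{binSize}-bp bins and counts, for
#' every bin, how many samples have at least one TAD boundary within the
#' bin or its directly neighboring bins (a +/-1-bin smoothing window; a
#' sample contributes at most once per bin). Edge bins use their existing
#' neighbors only.
#'
#' @param sets list of boundary sets, one per sample; each either a GRanges
#'   of 1-bp boundary positions or a data.frame with columns \code{chrom}
#'   and \code{pos} (0-based bp).
#' @param binSize bin width in bp, default 40000.
#' @param chromLengths named numeric of chromosome lengths (bp).
#' @return named list (per chromosome) of integer count vectors.
#' @export
binBoundaryCounts <- function(sets, binSize = 40000, chromLengths) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  counts <- lapply(chromLengths, function(len)
    integer(ceiling(len / binSize)))
  for (s in sets) {
    df <- boundaryFrame(s)
    for (chrom in unique(df$chrom)) {
      if (!chrom %in% names(counts))
        stop("boundary on chromosome without known length: ", chrom)
      nbins <- length(counts[[chrom]])
      b <- unique(binIndex0(df$pos[df$chrom == chrom], binSize))
      if (any(b < 0 | b >= nbins))
        stop("boundary position outside chromosome bounds on ", chrom)
      touched <- unique(pmin(pmax(c(b - 1L, b, b + 1L), 0L), nbins - 1L))
      counts[[chrom]][touched + 1L] <- counts[[chrom]][touched + 1L] + 1L
    }
  }
  counts
}

boundaryFrame <- function(s) {
  if (is(s, "GRanges"))
    data.frame(chrom = as.character(seqnames(s)), pos = start(s) - 1)
  else if (is.data.frame(s) && all(c("chrom", "pos") %in% names(s)))
    data.frame(chrom = as.character(s$chrom), pos = s$pos)
  else stop("boundary set must be a GRanges or a chrom/pos data.frame")
}

#' Call consensus TAD boundaries from smoothed bin counts
#'
#' Scans each chromosome left to right over the counts from
#' [binBoundaryCounts()]. A bin whose count strictly exceeds
#' \code{minExceed} opens a boundary region of that bin's extent; while the
#' next bin also exceeds \code{minExceed} the region is extended by that
#' bin; when the criterion fails the region closes and its boundary
#' position is the region start plus half the region length (integer floor).
#' Scanning resumes after the closed region.
#'
#' @param counts per-chromosome count vectors from [binBoundaryCounts()].
#' @param minExceed the count a bin must strictly exceed to qualify,
#'   default 2 (i.e. at least 3 supporting samples).
#' @param binSize bin width in bp used to build \code{counts}, default
#'   40000.
#' @return GRanges of boundary regions with metadata columns
#'   \code{position} (0-based bp of the consensus boundary point) and
#'   \code{maxCount}.
#' @export
callConsensusBoundaries <- function(counts, minExceed = 2, binSize = 40000) {
  stopifnot(is.list(counts))
  out <- lapply(names(counts), function(chrom) {
    v <- counts[[chrom]]
    qual <- v > minExceed
    if (!any(qual)) return(GRanges())
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    b0 <- starts[keep] - 1L
    b1 <- ends[keep] - 1L
    s0 <- b0 * binSize                 # region start, 0-based
    e0 <- (b1 + 1L) * binSize          # region end, 0-based exclusive
    pos <- s0 + (e0 - s0) %/% 2
    mx <- mapply(function(a, b) max(v[(a + 1L):(b + 1L)]), b0, b1)
    GRanges(chrom, IRanges(s0 + 1, e0),
            position = as.numeric(pos), maxCount = as.numeric(mx))
  })
  res <- suppressWarnings(do.call(c, out))
  if (!length(res)) {
    res <- GRanges()
    mcols(res) <- DataFrame(position = numeric(), maxCount = numeric())
  }
  sort(res)
}

#' One-call consensus boundary pipeline
#'
#' Convenience wrapper running [binBoundaryCounts()] then
#' [callConsensusBoundaries()].
#'
#' @inheritParams binBoundaryCounts
#' @inheritParams callConsensusBoundaries
#' @return see [callConsensusBoundaries()]
#' @export
consensusBoundaries <- function(sets, binSize = 40000, minExceed = 2,
                                chromLengths) {
  callConsensusBoundaries(
    binBoundaryCounts(sets, binSize = binSize, chromLengths = chromLengths),
    minExceed = minExceed, binSize = binSize)
}
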