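# Peak handling: enrichment detection on density tracks, blacklist
# filtering, ROSE-style super-enhancer stitching and ranking, union regions
# across samples, and tumor-vs-normal differential classification of
# average fragment density.

#' Detect enriched regions on a density track
#'
#' A deliberately simple enrichment detector used to close the synthetic
#' testing loop (production peak calls from MACS/SICER can be supplied as
#' BED instead): maximal runs of at least \code{minBins} consecutive bins
#' whose count reaches \code{foldThreshold} times the genome-wide median of
#' nonzero bin counts. Peak signal is the mean bin count of the run; the
#' summit is the center of the run's highest bin.
#'
#' @param track a [DensityTrack-class]
#' @param foldThreshold enrichment multiple of the median nonzero bin
#'   count (> 1), default 4.
#' @param minBins minimum run length in bins, default 3.
#' @return GRanges of peaks with metadata columns \code{signal} (mean bin
#'   count) and \code{summit} (0-based bp of the max bin's center).
#' @export
detectEnrichedRegions <- function(track, foldThreshold = 4, minBins = 3) {
  stopifnot(is(track, "DensityTrack"))
  if (foldThreshold <= 1) stop("foldThreshold must exceed 1")
  if (minBins < 1) stop("minBins must be at least 1")
  allCounts <- unlist(track@bins, use.names = FALSE)
  nz <- allCounts[allCounts > 0]
  if (!length(nz)) return(emptyPeaks())
  thr <- foldThreshold * median(nz)
  bs <- track@binSize
  out <- lapply(names(track@bins), function(chrom) {
    v <- track@bins[[chrom]]
    r <- rle(v >= thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minBins
    if (!any(keep)) return(emptyPeaks())
    b0 <- starts[keep] - 1L   # 0-based first bin
    b1 <- ends[keep] - 1L     # 0-based last bin
    len <- track@chromLengths[[chrom]]
    signal <- mapply(function(a, b) mean(v[(a + 1L):(b + 1L)]), b0, b1)
    summitBin <- mapply(function(a, b) {
      seg <- v[(a + 1L):(b + 1L)]
      a + which.max(seg) - 1L
    }, b0, b1)
    GRanges(chrom,
            IRanges(b0 * bs + 1, pmin((b1 + 1L) * bs, len)),
            signal = as.numeric(signal),
            summit = as.numeric(summitBin * bs + bs %/% 2))
  })
  res <- suppressWarnings(do.call(c, out))
  sort(res)
}

emptyPeaks <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(signal = numeric(), summit = numeric())
  gr
}

#' Remove peaks overlapping blacklisted regions
#'
#' Drops every peak whose interval overlaps a blacklist interval (such as
#' the ENCODE blacklist) by at least one bp.
#'
#' @param peaks GRanges of peaks
#' @param blacklist GRanges of blacklisted intervals (e.g. from
#'   [readBed()]); an empty blacklist is the identity.
#' @return the retained peaks
#' @export
filterBlacklist <- function(peaks, blacklist) {
  stopifnot(is(peaks, "GRanges"), is(blacklist, "GRanges"))
  if (!length(blacklist) || !length(peaks)) return(peaks)
  hits <- findOverlaps(peaks, blacklist, minoverlap = 1L)
  if (!length(hits)) return(peaks)
  peaks[-unique(queryHits(hits))]
}

#' Stitch peaks into merged regions
#'
#' Single-linkage stitching in the style of ROSE super-enhancer analysis:
#' peaks whose inter-interval gap is at most \code{gap} bp end up in the
#' same merged region (transitively), whose interval is the hull of its
#' constituents. The aggregate signal of a region is the sum over
#' constituents of signal x peak length, i.e. total fragment-density mass.
#'
#' @param peaks GRanges of one sample's peaks with a \code{signal} column.
#' @param gap maximum stitching distance in bp (gap between the end of one
#'   peak and the start of the next, end-exclusive), default 12500.
#' @return GRanges of merged regions with metadata columns
#'   \code{aggregateSignal}, \code{nConstituents} and \code{revmap}
#'   (constituent peak indices).
#' @export
stitchRegions <- function(peaks, gap = 12500) {
  stopifnot(is(peaks, "GRanges"))
  if (!length(peaks)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(aggregateSignal = numeric(),
                           nConstituents = integer())
    return(gr)
  }
  signal <- if (!is.null(peaks$signal)) peaks$signal else rep(1, length(peaks))
  # gapwidth between [.,e] and [s,.] is s-e-1 in 1-based closed coords,
  # which equals the 0-based end-exclusive distance; merge when <= gap
  merged <- reduce(peaks, min.gapwidth = gap + 1, with.revmap = TRUE,
                   ignore.strand = TRUE)
  agg <- vapply(merged$revmap, function(idx)
    sum(signal[idx] * width(peaks)[idx]), numeric(1))
  merged$aggregateSignal <- agg
  merged$nConstituents <- lengths(merged$revmap)
  merged
}

#' Flag super-enhancers among merged regions
#'
#' Ranks merged regions by aggregate signal (ties broken by earlier start)
#' and flags the strongest \code{max(1, floor(topFrac * N))} as
#' super-enhancers — the "top 5%" rule, with a minimum of one so the call is
#' defined for small region sets.
#'
#' @param regions GRanges from [stitchRegions()] with
#'   \code{aggregateSignal}.
#' @param topFrac fraction of regions to flag, default 0.05.
#' @return \code{regions} with added metadata columns \code{rank} (1 =
#'   strongest) and \code{isSuperEnhancer}.
#' @export
callSuperEnhancers <- function(regions, topFrac = 0.05) {
  stopifnot(is(regions, "GRanges"))
  if (!length(regions)) {
    regions$rank <- integer()
    regions$isSuperEnhancer <- logical()
    return(regions)
  }
  if (is.null(regions$aggregateSignal))
    stop("regions must carry aggregateSignal (see stitchRegions)")
  ord <- order(-regions$aggregateSignal, start(regions))
  rank <- integer(length(regions))
  rank[ord] <- seq_along(ord)
  nFlag <- max(1L, floor(topFrac * length(regions)))
  regions$rank <- rank
  regions$isSuperEnhancer <- rank <= nFlag
  regions
}

#' Union of peak sets across samples
#'
#' The minimal set of disjoint intervals covering every peak of every
#' sample ("extended regions for which at least one sample contains a
#' peak"). Overlapping and directly adjacent (zero-gap) peaks are merged.
#'
#' @param peakSets list of GRanges (one per sample), or a single GRanges.
#' @return GRanges of disjoint union regions.
#' @export
unionRegions <- function(peakSets) {
  if (is(peakSets, "GRanges")) peakSets <- list(peakSets)
  stopifnot(length(peakSets) >= 1L)
  all <- suppressWarnings(do.call(c, unname(lapply(peakSets, granges))))
  sort(reduce(all, min.gapwidth = 1L, ignore.strand = TRUE))
}

#' Classify differential regulatory regions between tumor and normal
#'
#' For each region (typically the union of peaks across samples) the mean
#' bin density is computed per sample over the bins the region overlaps.
#' The tumor statistic is the arithmetic mean over tumor samples; the
#' region's log2 ratio is \code{log2((tumor + eps) / (normal + eps))} and
#' the class is \code{up} when the ratio is at least \code{lfc},
#' \code{down} when at most \code{-lfc}, otherwise \code{neutral}. Tracks
#' must be depth-normalized (see [downsampleToMin()]) and binned
#' identically.
#'
#' @param regions GRanges of regions to classify.
#' @param tumorTracks list of [DensityTrack-class] for tumor samples.
#' @param normalTrack a [DensityTrack-class] for the normal sample.
#' @param lfc log2 fold-change threshold, default 2.
#' @param eps pseudocount in mean-bin-density units guarding zero
#'   densities, default 0.25.
#' @return GRanges with metadata columns \code{meanDensityTumor} (matrix
#'   column per tumor sample collapsed to its mean), \code{meanDensityNormal},
#'   \code{log2Ratio}, \code{class}, plus a \code{perSample} matrix of the
#'   per-sample means.
#' @export
classifyDifferential <- function(regions, tumorTracks, normalTrack,
                                 lfc = 2, eps = 0.25) {
  stopifnot(is(regions, "GRanges"))
  if (is(tumorTracks, "DensityTrack")) tumorTracks <- list(tumorTracks)
  stopifnot(length(tumorTracks) >= 1L, is(normalTrack, "DensityTrack"))
  tracks <- c(tumorTracks, list(normal = normalTrack))
  bs <- vapply(tracks, function(t) t@binSize, integer(1))
  if (length(unique(bs)) != 1L) stop("tracks must share one bin size")
  perSample <- vapply(tracks, function(t) regionMeanDensity(t, regions),
                      numeric(length(regions)))
  perSample <- matrix(perSample, nrow = length(regions),
                      dimnames = list(NULL, names(tracks)))
  nT <- length(tumorTracks)
  tumorMean <- unname(rowMeans(perSample[, seq_len(nT), drop = FALSE]))
  normalMean <- unname(perSample[, nT + 1L])
  ratio <- log2((tumorMean + eps) / (normalMean + eps))
  cls <- unname(ifelse(ratio >= lfc, "up",
                       ifelse(ratio <= -lfc, "down", "neutral")))
  regions$meanDensityTumor <- tumorMean
  regions$meanDensityNormal <- normalMean
  regions$log2Ratio <- ratio
  regions$class <- cls
  mcols(regions)$perSample <- perSample
  regions
}

# mean bin count of a track over the bins each region overlaps
regionMeanDensity <- function(track, regions) {
  bs <- track@binSize
  vapply(seq_along(regions), function(i) {
    chrom <- as.character(seqnames(regions)[i])
    if (!chrom %in% names(track@bins))
      stop("region on chromosome absent from track: ", chrom)
    v <- track@bins[[chrom]]
    len <- track@chromLengths[[chrom]]
    if (end(regions)[i] > len || start(regions)[i] < 1)
      stop("region outside track bounds on ", chrom)
    b0 <- (start(regions)[i] - 1L) %/% bs
    b1 <- (end(regions)[i] - 1L) %/% bs
    mean(v[(b0 + 1L):(b1 + 1L)])
  }, numeric(1))
}
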