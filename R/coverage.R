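# ChIP tag -> fragment-density pipeline: in-silico 3' extension of tag 5'
# ends, fixed-width binning, and depth normalization by downsampling every
# sample to the smallest library.

#' Extend ChIP-seq tags in silico to fragment intervals
#'
#' The 5' end of an aligned read (a "tag") marks one end of the
#' immunoprecipitated fragment, so each tag is extended at its 3' end to the
#' library's average fragment length. A + tag at 0-based position p becomes
#' the fragment \code{[p, p+L)}; a - tag at p (p being the rightmost, 5'
#' base) becomes \code{[p+1-L, p+1)}. Fragments are clipped to the
#' chromosome.
#'
#' @param tags data.frame with columns \code{chrom}, \code{pos} (0-based 5'
#'   coordinate) and \code{strand} ("+" or "-"), as produced by
#'   [generateChipTags()] or [readTagTable()].
#' @param fragmentLength target fragment length in bp; 150-250 is the
#'   usual size-selected range (a warning is emitted outside it), default
#'   200.
#' @param chromLengths named numeric of chromosome lengths (bp).
#' @return GRanges of fragment intervals (1-based, as usual for GRanges;
#'   the 0-based half-open fragment \code{[s, e)} is \code{GRanges(s+1, e)})
#'   with seqlengths set.
#' @examples
#' tags <- data.frame(chrom = "chr4s", pos = c(100, 499), strand = c("+", "-"))
#' extendTags(tags, 200, c(chr4s = 1e6))
#' @export
extendTags <- function(tags, fragmentLength = 200, chromLengths) {
  stopifnot(is.data.frame(tags),
            all(c("chrom", "pos", "strand") %in% names(tags)))
  if (fragmentLength < 1) stop("fragmentLength must be positive")
  if (fragmentLength < 150 || fragmentLength > 250)
    warning("fragmentLength ", fragmentLength,
            " outside the usual size-selected range of 150-250 bp")
  bad <- setdiff(unique(as.character(tags$strand)), c("+", "-"))
  if (length(bad))
    stop("unknown strand symbol: ", paste(bad, collapse = ", "))
  if (!all(unique(tags$chrom) %in% names(chromLengths)))
    stop("tag chromosome missing from chromLengths")
  lens <- chromLengths[as.character(tags$chrom)]
  if (any(tags$pos < 0 | tags$pos >= lens))
    stop("tag position outside chromosome bounds")
  fwd <- tags$strand == "+"
  # 0-based half-open fragment coordinates, then clip
  s0 <- ifelse(fwd, tags$pos, tags$pos + 1 - fragmentLength)
  e0 <- ifelse(fwd, tags$pos + fragmentLength, tags$pos + 1)
  s0 <- pmax(s0, 0)
  e0 <- pmin(e0, lens)
  gr <- GRanges(as.character(tags$chrom), IRanges(s0 + 1, e0),
                strand = as.character(tags$strand))
  seqlengths(gr) <- chromLengths[seqlevels(gr)]
  gr
}

#' Bin fragment intervals into a fixed-width density track
#'
#' Divides each chromosome into \code{binSize}-bp bins and counts, for every
#' bin, the number of fragments whose interval overlaps it. A fragment
#' increments every bin it overlaps, matching the visual density semantics
#' of a bedGraph coverage track.
#'
#' @param fragments GRanges of fragment intervals, e.g. from
#'   [extendTags()]. Seqlengths must be set unless \code{chromLengths} is
#'   given.
#' @param binSize bin width in bp, default 32.
#' @param chromLengths optional named numeric overriding
#'   \code{seqlengths(fragments)}.
#' @return a [DensityTrack-class]
#' @export
binDensity <- function(fragments, binSize = 32, chromLengths = NULL) {
  stopifnot(is(fragments, "GRanges"))
  if (binSize < 1) stop("binSize must be positive")
  binSize <- as.integer(binSize)
  if (is.null(chromLengths)) {
    chromLengths <- seqlengths(fragments)
    if (any(is.na(chromLengths)))
      stop("fragments must carry seqlengths (or pass chromLengths)")
  }
  chromLengths <- chromLengths[!is.na(chromLengths)]
  bins <- lapply(names(chromLengths), function(chrom) {
    len <- chromLengths[[chrom]]
    nbins <- as.integer(ceiling(len / binSize))
    fr <- fragments[as.character(seqnames(fragments)) == chrom]
    counts <- numeric(nbins)
    if (length(fr)) {
      if (min(start(fr)) < 1 || max(end(fr)) > len)
        stop("fragment outside chromosome bounds on ", chrom)
      b0 <- (start(fr) - 1L) %/% binSize        # first overlapped bin
      b1 <- (end(fr) - 1L) %/% binSize          # last overlapped bin
      # difference-array accumulation: +1 at b0, -1 past b1, then cumsum
      delta <- numeric(nbins + 1L)
      add <- tabulate(b0 + 1L, nbins = nbins + 1L)
      subq <- tabulate(b1 + 2L, nbins = nbins + 1L)
      counts <- cumsum(add - subq)[seq_len(nbins)]
    }
    counts
  })
  names(bins) <- names(chromLengths)
  chromMissing <- !as.character(seqnames(fragments)) %in% names(chromLengths)
  if (any(chromMissing)) stop("fragment on chromosome without known length")
  new("DensityTrack", bins = bins, binSize = binSize,
      chromLengths = setNames(as.numeric(chromLengths), names(chromLengths)),
      totalFragments = as.numeric(length(fragments)))
}

#' Normalize ChIP samples by downsampling to the smallest library
#'
#' Before peak calling or density comparison, all samples of one ChIP/IP are
#' brought to the same depth by sampling each down, uniformly without
#' replacement, to the tag count of the smallest sample. The smallest sample
#' is returned unchanged.
#'
#' @param samples list of tag data.frames (columns chrom, pos, strand).
#' @param seed integer seed; subsampling is deterministic under it.
#' @return list of tag data.frames, all with the same number of rows.
#' @export
downsampleToMin <- function(samples, seed = 1L) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  n <- vapply(samples, nrow, integer(1))
  if (any(n == 0L)) stop("empty tag sample cannot be downsampled")
  m <- min(n)
  withSeed(seed, {
    lapply(samples, function(df) {
      if (nrow(df) == m) return(df)
      keep <- sort(sample.int(nrow(df), m))
      df[keep, , drop = FALSE]
    })
  })
}

#' Write / read a density track as bedGraph
#'
#' The bedGraph is 0-based half-open with one line per bin, or with runs of
#' equal-valued adjacent bins merged into one line
#' (\code{mergeRuns = TRUE}, the usual dialect). Header comment lines record
#' the bin size, chromosome lengths and fragment count so the track
#' round-trips exactly.
#'
#' @param track a [DensityTrack-class]
#' @param file path to write / read
#' @param mergeRuns merge runs of equal-valued adjacent bins (writer only)
#' @return \code{readBedGraph} returns a [DensityTrack-class];
#'   \code{writeBedGraph} returns \code{file} invisibly.
#' @export
writeBedGraph <- function(track, file, mergeRuns = TRUE) {
  stopifnot(is(track, "DensityTrack"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# binSize=%d", track@binSize),
    sprintf("# totalFragments=%g", track@totalFragments),
    sprintf("# chromLengths=%s",
            paste(sprintf("%s:%g", names(track@chromLengths),
                          track@chromLengths), collapse = ",")),
    "track type=bedGraph"
  ), con)
  for (chrom in names(track@bins)) {
    v <- track@bins[[chrom]]
    if (!length(v)) next
    len <- track@chromLengths[[chrom]]
    if (mergeRuns) {
      r <- rle(v)
      endBin <- cumsum(r$lengths)
      startBin <- endBin - r$lengths
      vals <- r$values
    } else {
      startBin <- seq_along(v) - 1L
      endBin <- seq_along(v)
      vals <- v
    }
    s0 <- startBin * track@binSize
    e0 <- pmin(endBin * track@binSize, len)
    writeLines(sprintf("%s\t%g\t%g\t%g", chrom, s0, e0, vals), con)
  }
  invisible(file)
}

#' @rdname writeBedGraph
#' @export
readBedGraph <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  getHdr <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) stop("bedGraph header missing ", key)
    sub(sprintf("^# %s=", key), "", m[1])
  }
  binSize <- as.integer(getHdr("binSize"))
  totalFragments <- as.numeric(getHdr("totalFragments"))
  clPairs <- strsplit(strsplit(getHdr("chromLengths"), ",")[[1]], ":")
  chromLengths <- setNames(
    vapply(clPairs, function(p) as.numeric(p[2]), numeric(1)),
    vapply(clPairs, `[`, character(1), 1))
  bins <- lapply(chromLengths, function(len) numeric(ceiling(len / binSize)))
  dataIdx <- which(!grepl("^#", lines) & !grepl("^track", lines) &
                     nzchar(lines))
  for (i in dataIdx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L || anyNA(suppressWarnings(as.numeric(f[2:4]))))
      stop("malformed bedGraph line ", i, ": ", lines[i])
    chrom <- f[1]
    if (!chrom %in% names(bins))
      stop("malformed bedGraph line ", i, ": unknown chromosome ", chrom)
    s0 <- as.numeric(f[2]); e0 <- as.numeric(f[3]); val <- as.numeric(f[4])
    if (s0 %% binSize != 0 || s0 >= e0)
      stop("malformed bedGraph line ", i, ": interval off the bin grid")
    b <- seq(s0 %/% binSize + 1L, ceiling(e0 / binSize))
    bins[[chrom]][b] <- val
  }
  new("DensityTrack", bins = bins, binSize = binSize,
      chromLengths = chromLengths, totalFragments = totalFragments)
}
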