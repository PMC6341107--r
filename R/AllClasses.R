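# S4 containers for the pipeline's central objects.
#
# Interval data (peaks, fragments, boundaries, merged regions) travel as
# GRanges; these classes hold the structures GRanges does not model: binned
# density vectors, the two-locus simulation model, and calibrated PWMs.

#' DensityTrack: binned ChIP fragment density
#'
#' Per-chromosome fixed-width bin counts of extended ChIP fragments. A
#' fragment contributes one count to every bin its interval overlaps, so the
#' track mirrors the visual density semantics of a bedGraph coverage track.
#'
#' @slot bins named list, one numeric vector of bin counts per chromosome;
#'   vector length is \code{ceiling(chromLength / binSize)}.
#' @slot binSize integer bin width in bp (the pipeline default is 32).
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot totalFragments numeric, number of fragments binned into the track.
#'
#' @seealso [binDensity()], [writeBedGraph()], [readBedGraph()]
#' @export
setClass("DensityTrack",
  representation(
    bins = "list",
    binSize = "integer",
    chromLengths = "numeric",
    totalFragments = "numeric"
  )
)

setValidity("DensityTrack", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || object@binSize < 1L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (is.null(names(object@bins)) || is.null(names(object@chromLengths)))
    msg <- c(msg, "bins and chromLengths must be named")
  if (!setequal(names(object@bins), names(object@chromLengths)))
    msg <- c(msg, "bins and chromLengths must cover the same chromosomes")
  for (chrom in names(object@bins)) {
    v <- object@bins[[chrom]]
    expected <- ceiling(object@chromLengths[[chrom]] / object@binSize)
    if (length(v) != expected)
      msg <- c(msg, sprintf(
        "chromosome %s: %d bins, expected ceiling(%d/%d) = %d",
        chrom, length(v), object@chromLengths[[chrom]], object@binSize,
        expected))
    if (any(v < 0)) msg <- c(msg, sprintf("negative bin count on %s", chrom))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DensityTrack construct a track from bin-count vectors
#' @param bins named list of per-chromosome bin-count vectors
#' @param binSizeBp bin width in bp
#' @param chromLengths named chromosome lengths (bp)
#' @param totalFragments fragment count behind the track (defaults to the
#'   sum of all bins, an upper bound used only for bookkeeping)
#' @export
densityTrack <- function(bins, binSizeBp = 32, chromLengths = NULL,
                         totalFragments = NULL) {
  if (is.null(chromLengths))
    chromLengths <- vapply(bins, function(v) length(v) * binSizeBp,
                           numeric(1))
  if (is.null(totalFragments))
    totalFragments <- sum(vapply(bins, sum, numeric(1)))
  new("DensityTrack", bins = lapply(bins, as.numeric),
      binSize = as.integer(binSizeBp),
      chromLengths = setNames(as.numeric(chromLengths),
                              names(chromLengths)),
      totalFragments = as.numeric(totalFragments))
}

#' @describeIn DensityTrack bin width in bp
#' @param track,object a \code{DensityTrack}
#' @export
binSize <- function(track) {
  stopifnot(is(track, "DensityTrack"))
  track@binSize
}

#' @describeIn DensityTrack bin-count vector for one chromosome (or the
#'   full named list when \code{chrom} is missing)
#' @param chrom chromosome name
#' @export
binCounts <- function(track, chrom) {
  stopifnot(is(track, "DensityTrack"))
  if (missing(chrom)) return(track@bins)
  if (!chrom %in% names(track@bins))
    stop("chromosome not in track: ", chrom)
  track@bins[[chrom]]
}

#' @describeIn DensityTrack named chromosome lengths (bp)
#' @export
trackChromLengths <- function(track) {
  stopifnot(is(track, "DensityTrack"))
  track@chromLengths
}

#' @describeIn DensityTrack number of fragments binned into the track
#' @export
totalFragments <- function(track) {
  stopifnot(is(track, "DensityTrack"))
  track@totalFragments
}

setMethod("show", "DensityTrack", function(object) {
  cat("DensityTrack with", length(object@bins), "chromosome(s),",
      "bin size", object@binSize, "bp\n")
  for (chrom in names(object@bins)) {
    v <- object@bins[[chrom]]
    cat(sprintf("  %s: %d bins, total count %g\n", chrom, length(v), sum(v)))
  }
  cat("  fragments:", object@totalFragments, "\n")
})

#' LocusModel: two-locus enhancer-hijacking simulation model
#'
#' Describes a donor locus (an SCPP-like salivary gland gene cluster:
#' clustered high-signal enhancers, convergent CTCF sites, an FDCSP-like
#' gene with introns and a triple-gene span of the most abundantly
#' expressed cluster genes) and an acceptor locus (an NR4A3-like
#' proto-oncogene TSS with a CTCF site upstream). Every synthetic input the
#' pipeline consumes is generated from this model, so planted truth is
#' always traceable.
#'
#' @slot donorChrom,acceptorChrom chromosome names (defaults "chr4s",
#'   "chr9s"; the "s" marks synthetic coordinates, not a genome build).
#' @slot chromLengths named numeric, lengths of both chromosomes (bp).
#' @slot donorEnhancers GRanges with metadata column \code{fold} (> 1), the
#'   per-bp tag-rate multiplier of each planted enhancer.
#' @slot donorCtcfSites GRanges of 1-bp CTCF site positions with strand
#'   giving motif orientation; includes one convergent (+ then -) pair.
#' @slot donorGenes GRanges of donor genes with metadata columns
#'   \code{gene_id} and \code{in_triple_span}.
#' @slot donorIntrons GRanges of donor introns with metadata columns
#'   \code{gene_id} and \code{intron_number}.
#' @slot acceptorTss 0-based TSS position on the acceptor chromosome.
#' @slot acceptorCtcfSite 0-based position of the acceptor CTCF site
#'   (13.5 kb upstream of the TSS by default).
#'
#' @seealso [generateLocus()], [patternRegions()]
#' @export
setClass("LocusModel",
  representation(
    donorChrom = "character",
    acceptorChrom = "character",
    chromLengths = "numeric",
    donorEnhancers = "GRanges",
    donorCtcfSites = "GRanges",
    donorGenes = "GRanges",
    donorIntrons = "GRanges",
    acceptorTss = "numeric",
    acceptorCtcfSite = "numeric"
  )
)

setValidity("LocusModel", function(object) {
  msg <- character()
  lens <- object@chromLengths
  need <- c(object@donorChrom, object@acceptorChrom)
  if (!all(need %in% names(lens)))
    msg <- c(msg, "chromLengths must name donor and acceptor chromosomes")
  donorLen <- lens[[object@donorChrom]]
  inBounds <- function(gr) length(gr) == 0L ||
    (min(start(gr)) >= 1L && max(end(gr)) <= donorLen)
  if (!inBounds(object@donorEnhancers))
    msg <- c(msg, "donor enhancer outside chromosome bounds")
  if (!inBounds(object@donorCtcfSites))
    msg <- c(msg, "donor CTCF site outside chromosome bounds")
  if (!inBounds(object@donorGenes))
    msg <- c(msg, "donor gene outside chromosome bounds")
  if (length(object@donorEnhancers) &&
      (is.null(object@donorEnhancers$fold) ||
       any(object@donorEnhancers$fold <= 1)))
    msg <- c(msg, "enhancer intensities (fold) must all exceed 1")
  accLen <- lens[[object@acceptorChrom]]
  if (object@acceptorTss < 0 || object@acceptorTss >= accLen)
    msg <- c(msg, "acceptor TSS outside chromosome bounds")
  if (object@acceptorCtcfSite >= object@acceptorTss)
    msg <- c(msg, "acceptor CTCF site must lie upstream of the TSS")
  # the triple-gene span and the convergent CTCF window must not overlap,
  # otherwise breakpoint patterns 1 and 2 would be confounded
  win <- tryCatch(ctcfPairWindow(object), error = function(e) NULL)
  triple <- tripleGeneSpan(object)
  if (!is.null(win) && !is.null(triple) &&
      length(findOverlaps(win, triple)) > 0L)
    msg <- c(msg, "CTCF-pair window overlaps the triple-gene span")
  if (length(msg)) msg else TRUE
})

#' @describeIn LocusModel planted donor enhancers (GRanges with
#'   \code{fold})
#' @param locus a \code{LocusModel}
#' @export
donorEnhancers <- function(locus) {
  stopifnot(is(locus, "LocusModel")); locus@donorEnhancers
}

#' @describeIn LocusModel oriented donor CTCF sites
#' @export
donorCtcfSites <- function(locus) {
  stopifnot(is(locus, "LocusModel")); locus@donorCtcfSites
}

#' @describeIn LocusModel donor gene intervals
#' @export
donorGenes <- function(locus) {
  stopifnot(is(locus, "LocusModel")); locus@donorGenes
}

#' @describeIn LocusModel donor intron intervals
#' @export
donorIntrons <- function(locus) {
  stopifnot(is(locus, "LocusModel")); locus@donorIntrons
}

#' @describeIn LocusModel acceptor TSS position (0-based)
#' @export
acceptorTss <- function(locus) {
  stopifnot(is(locus, "LocusModel")); locus@acceptorTss
}

#' @describeIn LocusModel acceptor CTCF site position (0-based)
#' @export
acceptorCtcfSite <- function(locus) {
  stopifnot(is(locus, "LocusModel")); locus@acceptorCtcfSite
}

#' @describeIn LocusModel named chromosome lengths (bp)
#' @export
chromLengths <- function(locus) {
  stopifnot(is(locus, "LocusModel")); locus@chromLengths
}

#' Window between the convergent CTCF pair of a locus model
#'
#' The open genomic window between the first convergent (forward site
#' immediately followed by a reverse site) CTCF pair on the donor
#' chromosome. Breakpoints falling here, outside any gene, define
#' rearrangement pattern 1.
#'
#' @param locus a [LocusModel-class]
#' @return GRanges of length 1
#' @export
ctcfPairWindow <- function(locus) {
  stopifnot(is(locus, "LocusModel"))
  sites <- sort(locus@donorCtcfSites, ignore.strand = TRUE)
  s <- as.character(strand(sites))
  conv <- which(s[-length(s)] == "+" & s[-1] == "-")
  if (!length(conv)) stop("locus has no convergent CTCF pair")
  i <- conv[1]
  GRanges(locus@donorChrom,
          IRanges(end(sites)[i] + 1L, start(sites)[i + 1L] - 1L))
}

#' Span of the three most abundantly expressed donor genes
#'
#' The hull of the genes flagged \code{in_triple_span} (the STATH/HTN3/HTN1
#' analogue of the model). Breakpoints falling here define rearrangement
#' pattern 2.
#'
#' @param locus a [LocusModel-class]
#' @return GRanges of length 1, or NULL if no genes are flagged
#' @export
tripleGeneSpan <- function(locus) {
  stopifnot(is(locus, "LocusModel"))
  g <- locus@donorGenes[locus@donorGenes$in_triple_span]
  if (!length(g)) return(NULL)
  GRanges(locus@donorChrom, IRanges(min(start(g)), max(end(g))))
}

setMethod("show", "LocusModel", function(object) {
  cat("LocusModel\n")
  cat(sprintf("  donor %s (%g bp): %d enhancers, %d CTCF sites, %d genes\n",
              object@donorChrom, object@chromLengths[[object@donorChrom]],
              length(object@donorEnhancers), length(object@donorCtcfSites),
              length(object@donorGenes)))
  cat(sprintf("  acceptor %s (%g bp): TSS at %d, CTCF site at %d (%d bp upstream)\n",
              object@acceptorChrom,
              object@chromLengths[[object@acceptorChrom]],
              object@acceptorTss, object@acceptorCtcfSite,
              object@acceptorTss - object@acceptorCtcfSite))
})

#' PWMotif: position weight matrix with calibrated score threshold
#'
#' Log-odds position weight matrix over \{A,C,G,T\} against an explicit
#' scanning background, optionally carrying the score threshold calibrated
#' to a target false-positive rate (see [calibrateThreshold()]).
#'
#' @slot name motif name.
#' @slot logOdds 4 x L numeric matrix, rows A, C, G, T (log2 odds).
#' @slot probs 4 x L matrix of pseudocount-regularized base probabilities.
#' @slot background named numeric of length 4 summing to 1.
#' @slot threshold numeric score threshold (NA before calibration).
#'
#' @seealso [buildPWM()], [scanSequence()]
#' @export
setClass("PWMotif",
  representation(
    name = "character",
    logOdds = "matrix",
    probs = "matrix",
    background = "numeric",
    threshold = "numeric"
  )
)

setValidity("PWMotif", function(object) {
  msg <- character()
  if (!identical(rownames(object@logOdds), c("A", "C", "G", "T")))
    msg <- c(msg, "logOdds rows must be A, C, G, T")
  if (ncol(object@logOdds) < 1L)
    msg <- c(msg, "motif must have at least one position")
  if (!identical(dim(object@probs), dim(object@logOdds)))
    msg <- c(msg, "probs and logOdds dimensions differ")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn PWMotif motif length (number of positions)
#' @param pwm a \code{PWMotif}
#' @export
motifLength <- function(pwm) {
  stopifnot(is(pwm, "PWMotif")); ncol(pwm@logOdds)
}

#' @describeIn PWMotif calibrated score threshold (NA if not calibrated)
#' @export
motifThreshold <- function(pwm) {
  stopifnot(is(pwm, "PWMotif")); pwm@threshold
}

#' @describeIn PWMotif 4 x L log2-odds matrix
#' @export
motifLogOdds <- function(pwm) {
  stopifnot(is(pwm, "PWMotif")); pwm@logOdds
}

#' @describeIn PWMotif scanning background probabilities
#' @export
motifBackground <- function(pwm) {
  stopifnot(is(pwm, "PWMotif")); pwm@background
}

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif \"%s\": %d positions, background A=%.2f C=%.2f G=%.2f T=%.2f\n",
              object@name, ncol(object@logOdds),
              object@background[["A"]], object@background[["C"]],
              object@background[["G"]], object@background[["T"]]))
  if (!is.na(object@threshold))
    cat(sprintf("  threshold: %.4f (log2-odds)\n", object@threshold))
  else cat("  threshold: not calibrated\n")
})
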