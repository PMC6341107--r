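# PWM construction, FPR-calibrated threshold (dynamic programming over the
# quantized score distribution, TFM-pvalue style), two-strand scanning,
# CTCF orientation annotation, and an exact-binomial motif enrichment test.

DNA_BASES <- c("A", "C", "G", "T")

# AT-rich human-genome scanning background: A=T=0.30, C=G=0.20 (~40% GC)
#' @export
#' @rdname buildPWM
humanBackground <- function() c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)

#' Build a log-odds PWM from a position frequency matrix
#'
#' Adds pseudocounts proportional to the background base composition (to
#' avoid overfitting sparse count matrices; the default background models a
#' genome of about 40% GC, A = T = 0.30 and C = G = 0.20), normalizes each
#' column, and converts to log2 odds against the scanning background.
#'
#' @param pfm 4 x L numeric count matrix with rows A, C, G, T (see
#'   [readPFM()] for the file reader, which auto-detects orientation).
#' @param pseudocountWeight total pseudocount mass added per column,
#'   distributed proportionally to the background; default 1. With weight 0
#'   the estimate is pure maximum likelihood (columns summing to zero are
#'   then an error).
#' @param background named base probabilities used both for pseudocounts
#'   and as scanning background.
#' @param name motif name.
#' @return a [PWMotif-class] (threshold not yet calibrated)
#' @examples
#' pfm <- matrix(c(10, 0, 0, 0), 4, 1, dimnames = list(c("A","C","G","T")))
#' buildPWM(pfm, 1)  # P(A) at the single position is 10.3/11
#' @export
buildPWM <- function(pfm, pseudocountWeight = 1,
                     background = humanBackground(), name = "motif") {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) stop("pfm must have 4 rows (A, C, G, T)")
  if (is.null(rownames(pfm))) rownames(pfm) <- DNA_BASES
  pfm <- pfm[DNA_BASES, , drop = FALSE]
  if (any(pfm < 0)) stop("pfm counts must be non-negative")
  if (ncol(pfm) < 1L) stop("pfm must have at least one position")
  background <- background[DNA_BASES]
  if (abs(sum(background) - 1) > 1e-8)
    stop("background must sum to 1")
  colTot <- colSums(pfm)
  if (pseudocountWeight <= 0 && any(colTot == 0))
    stop("zero-total pfm column requires a positive pseudocount weight")
  probs <- sweep(pfm + outer(background, rep(pseudocountWeight, ncol(pfm))),
                 2, colTot + pseudocountWeight, "/")
  logOdds <- log2(sweep(probs, 1, background, "/"))
  new("PWMotif", name = name, logOdds = logOdds, probs = probs,
      background = background, threshold = NA_real_)
}

#' Read a position frequency matrix from a whitespace-delimited file
#'
#' Accepts both the 4-rows-by-L-columns and the L-rows-by-4-columns
#' orientation (auto-detected; a 4 x 4 matrix is taken as rows = bases). A
#' leading header line naming the bases and a leading row-label column are
#' both tolerated.
#'
#' @param file path to the PFM text file
#' @return 4 x L numeric matrix with rows A, C, G, T
#' @export
readPFM <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[#>]", lines)]
  fields <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  # drop a header line made of base letters, and leading base labels
  isBase <- function(x) toupper(x) %in% DNA_BASES
  if (all(vapply(fields[[1]], isBase, logical(1))))
    fields <- fields[-1]
  labels <- vapply(fields, function(f) isBase(f[1]) &&
                     is.na(suppressWarnings(as.numeric(f[1]))), logical(1))
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (labels[i]) f <- f[-1]
    as.numeric(f)
  })
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop("non-numeric value in PFM file")
  if (all(labels)) {
    rownames(m) <- toupper(vapply(fields, `[`, character(1), 1))
    m <- m[DNA_BASES, , drop = FALSE]
  } else if (nrow(m) == 4L) {
    rownames(m) <- DNA_BASES
  } else if (ncol(m) == 4L) {
    m <- t(m)
    rownames(m) <- DNA_BASES
  } else stop("PFM must be 4 x L or L x 4")
  m
}

#' Calibrate a PWM score threshold to a target false-positive rate
#'
#' Computes, by dynamic programming over the distribution of quantized
#' per-position scores under an i.i.d. background, the smallest score s on
#' a grid of \code{precision} quantization steps such that
#' \code{P(score >= s | background) <= fpr}. This is the standard
#' TFM-pvalue-style calibration; with \code{precision = 1e4} the
#' quantization error is negligible for scanning.
#'
#' @param pwm a [PWMotif-class]
#' @param fpr target per-window false-positive rate, default 1e-4.
#' @param precision number of quantization steps of the total score range,
#'   default 1e4.
#' @return the input \code{pwm} with its \code{threshold} slot set; use
#'   [motifThreshold()] to read the value.
#' @export
calibrateThreshold <- function(pwm, fpr = 1e-4, precision = 1e4) {
  stopifnot(is(pwm, "PWMotif"))
  if (fpr <= 0 || fpr > 1) stop("fpr must be in (0, 1]")
  M <- pwm@logOdds
  L <- ncol(M)
  mins <- apply(M, 2, min)
  maxs <- apply(M, 2, max)
  range <- sum(maxs) - sum(mins)
  if (range == 0) {                     # degenerate flat motif
    pwm@threshold <- sum(mins)
    return(pwm)
  }
  delta <- range / precision
  Q <- quantizeScores(M, mins, delta)   # integer 4 x L, >= 0
  bg <- pwm@background
  dist <- 1
  offset <- 0L
  for (j in seq_len(L)) {
    qj <- Q[, j]
    newLen <- length(dist) + max(qj)
    nd <- numeric(newLen)
    for (b in 1:4) {
      idx <- seq_along(dist) + qj[b]
      nd[idx] <- nd[idx] + dist * bg[b]
    }
    dist <- nd
  }
  tail <- rev(cumsum(rev(dist)))        # tail[t+1] = P(Qsum >= t)
  t0 <- which(tail <= fpr + 1e-12)[1]
  achievable <- which(dist > 0) - 1L
  cand <- if (is.na(t0)) integer() else achievable[achievable >= t0 - 1L]
  # smallest ACHIEVABLE quantized score whose tail probability is <= fpr;
  # when even the maximal score is too probable, one step above it
  t <- if (length(cand)) min(cand) else max(achievable) + 1L
  pwm@threshold <- sum(mins) + t * delta
  pwm
}

quantizeScores <- function(M, mins, delta) {
  q <- floor(sweep(M, 2, mins, "-") / delta)
  storage.mode(q) <- "integer"
  q
}

#' Scan a sequence with a calibrated PWM on both strands
#'
#' Scores every length-L window on the forward sequence and on the reverse
#' complement; windows containing any non-ACGT base are skipped. A reverse
#' strand hit over forward-sequence window \code{[i, i+L)} is reported at
#' that interval with strand \code{-}. Scanning is case-insensitive.
#'
#' @param sequence a character string, DNAString, or length-1 DNAStringSet.
#' @param pwm a calibrated [PWMotif-class] (see [calibrateThreshold()]), or
#'   pass \code{threshold} explicitly.
#' @param seqname sequence name used in the returned GRanges, default
#'   "seq".
#' @param threshold score cutoff; defaults to the PWM's calibrated
#'   threshold.
#' @return GRanges of hits with metadata columns \code{score} and
#'   \code{pwm}; strand records the hit orientation.
#' @export
scanSequence <- function(sequence, pwm, seqname = "seq", threshold = NULL) {
  stopifnot(is(pwm, "PWMotif"))
  if (is.null(threshold)) threshold <- pwm@threshold
  if (is.na(threshold))
    stop("PWM has no calibrated threshold; run calibrateThreshold() first")
  seqChar <- asSequenceString(sequence)
  idx <- match(strsplit(toupper(seqChar), "", fixed = TRUE)[[1]], DNA_BASES)
  M <- pwm@logOdds
  L <- ncol(M)
  n <- length(idx)
  if (n < L) return(emptyHits())
  scoreWindows <- function(mat) {
    sc <- numeric(n - L + 1L)
    for (j in seq_len(L)) sc <- sc + unname(mat[, j])[idx[j:(j + n - L)]]
    sc
  }
  # reverse-complement PWM scores the - strand on the forward sequence
  Mrc <- M[4:1, L:1, drop = FALSE]
  rownames(Mrc) <- DNA_BASES
  fwd <- scoreWindows(M)
  rev <- scoreWindows(Mrc)
  iF <- which(fwd >= threshold)
  iR <- which(rev >= threshold)
  if (!length(iF) && !length(iR)) return(emptyHits())
  gr <- GRanges(seqname,
                IRanges(c(iF, iR), width = L),
                strand = rep(c("+", "-"), c(length(iF), length(iR))),
                score = c(fwd[iF], rev[iR]),
                pwm = pwm@name)
  sort(gr, ignore.strand = TRUE)
}

asSequenceString <- function(sequence) {
  if (is(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    as.character(sequence[[1]])
  } else if (is(sequence, "DNAString")) as.character(sequence)
  else if (is.character(sequence) && length(sequence) == 1L) sequence
  else stop("sequence must be a single character string or DNAString")
}

emptyHits <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(score = numeric(), pwm = character())
  gr
}

#' Annotate CTCF peaks with motif orientation
#'
#' Assigns each peak the strand of its best-scoring contained motif hit;
#' peaks containing no hit stay unoriented (\code{*}). Orientation maps of
#' CTCF sites built this way reveal convergent ("inversely oriented")
#' pairs, which mark sub-TAD borders.
#'
#' @param peaks GRanges of CTCF ChIP peaks.
#' @param hits GRanges of motif hits from [scanSequence()] (coordinates on
#'   the same chromosome naming as \code{peaks}).
#' @return \code{peaks} with strand set to the best hit's orientation and
#'   metadata columns \code{bestHitScore} (NA when unoriented).
#' @export
annotateCtcfOrientation <- function(peaks, hits) {
  stopifnot(is(peaks, "GRanges"), is(hits, "GRanges"))
  strand(peaks) <- "*"
  peaks$bestHitScore <- NA_real_
  if (!length(peaks) || !length(hits)) return(peaks)
  ov <- findOverlaps(hits, peaks, type = "within", ignore.strand = TRUE)
  if (!length(ov)) return(peaks)
  df <- data.frame(hit = queryHits(ov), peak = subjectHits(ov),
                   score = hits$score[queryHits(ov)])
  best <- df[order(df$peak, -df$score), ]
  best <- best[!duplicated(best$peak), ]
  strand(peaks)[best$peak] <- as.character(strand(hits))[best$hit]
  peaks$bestHitScore[best$peak] <- best$score
  peaks
}

#' Find convergent (inversely oriented) site pairs
#'
#' Walks oriented sites in genomic order and flags each adjacent pair whose
#' left member is on the forward strand and whose right member is on the
#' reverse strand — the convergent configuration of insulator CTCF sites at
#' sub-TAD borders.
#'
#' @param sites GRanges of oriented sites (strand + or -; unoriented sites
#'   are ignored).
#' @return GRanges of the windows strictly between the members of each
#'   convergent pair, with metadata columns \code{leftSite} and
#'   \code{rightSite} (indices into the oriented, sorted sites).
#' @export
convergentPairs <- function(sites) {
  stopifnot(is(sites, "GRanges"))
  sites <- sites[as.character(strand(sites)) %in% c("+", "-")]
  sites <- sort(sites, ignore.strand = TRUE)
  if (length(sites) < 2L) return(GRanges())
  out <- list()
  for (chrom in unique(as.character(seqnames(sites)))) {
    s <- sites[as.character(seqnames(sites)) == chrom]
    if (length(s) < 2L) next
    str <- as.character(strand(s))
    i <- which(str[-length(str)] == "+" & str[-1] == "-")
    if (!length(i)) next
    out[[chrom]] <- GRanges(chrom,
                            IRanges(end(s)[i] + 1L, start(s)[i + 1L] - 1L),
                            leftSite = i, rightSite = i + 1L)
  }
  if (!length(out)) return(GRanges())
  suppressWarnings(do.call(c, unname(out)))
}

#' Exact-binomial motif enrichment of foreground vs background regions
#'
#' Tests whether the fraction of foreground sequences containing at least
#' one motif hit exceeds the background fraction, by a one-sided exact
#' binomial test of the foreground hit count against the background
#' hit-containing fraction. The intended background is the complete set of
#' extended (union) regions of the same histone mark.
#'
#' @param fgSeqs,bgSeqs character vectors or DNAStringSets of region
#'   sequences.
#' @param pwm a calibrated [PWMotif-class].
#' @return list with \code{fgFraction}, \code{bgFraction}, \code{pValue},
#'   \code{nFg}, \code{nBg}.
#' @export
motifEnrichment <- function(fgSeqs, bgSeqs, pwm) {
  fg <- asSequenceVector(fgSeqs)
  bg <- asSequenceVector(bgSeqs)
  if (!length(fg)) stop("foreground region set is empty")
  if (!length(bg)) stop("background region set is empty")
  hasHit <- function(s) length(scanSequence(s, pwm)) > 0L
  x <- sum(vapply(fg, hasHit, logical(1)))
  bgFrac <- mean(vapply(bg, hasHit, logical(1)))
  n <- length(fg)
  p <- if (bgFrac <= 0) {
    if (x > 0) 0 else 1
  } else if (bgFrac >= 1) 1
  else binom.test(x, n, p = bgFrac, alternative = "greater")$p.value
  list(fgFraction = x / n, bgFraction = bgFrac, pValue = p,
       nFg = n, nBg = length(bg))
}

asSequenceVector <- function(seqs) {
  if (is(seqs, "DNAStringSet")) as.character(seqs)
  else if (is.character(seqs)) seqs
  else stop("sequences must be character or DNAStringSet")
}
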