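# Independent brute-force oracles. Each reimplements an operation by the
# most direct method available (per-bp sweeps, union-find, exhaustive
# enumeration) so the package's algorithmic implementations can be checked
# against them on random instances. None of them share code with R/.

# per-bin fragment overlap counts by direct looping over bins
oracleBinCounts <- function(s0, e0, chromLen, binSize) {
  nbins <- ceiling(chromLen / binSize)
  counts <- numeric(nbins)
  for (b in seq_len(nbins) - 1) {
    bs <- b * binSize
    be <- min((b + 1) * binSize, chromLen)
    counts[b + 1] <- sum(s0 < be & e0 > bs)
  }
  counts
}

# single-linkage stitching via union-find over all pairs
oracleStitch <- function(s0, e0, gap) {
  n <- length(s0)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- max(s0[j] - e0[i], s0[i] - e0[j], 0)
    if (d <= gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(comp), function(c) {
    idx <- which(comp == c)
    c(min(s0[idx]), max(e0[idx]))
  })
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

# union of intervals by per-bp mark and sweep
oracleUnion <- function(s0, e0, chromLen) {
  marked <- logical(chromLen)
  for (i in seq_along(s0))
    if (e0[i] > s0[i]) marked[(s0[i] + 1):e0[i]] <- TRUE
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values], ends[r$values])
}

# consensus TAD boundaries: smear each sample's boundary bins by +/-1,
# count samples per bin, mark bins with count > minExceed, take maximal
# runs, report midpoints
oracleConsensus <- function(posPerSample, nbins, binSize, minExceed = 2) {
  counts <- integer(nbins)
  for (pos in posPerSample) {
    b <- unique(floor(pos / binSize))
    touched <- unique(pmin(pmax(c(b - 1, b, b + 1), 0), nbins - 1))
    counts[touched + 1] <- counts[touched + 1] + 1L
  }
  qual <- which(counts > minExceed) - 1
  if (!length(qual)) return(numeric(0))
  runs <- split(qual, cumsum(c(1, diff(qual) != 1)))
  vapply(runs, function(b) {
    s <- min(b) * binSize
    e <- (max(b) + 1) * binSize
    s + (e - s) %/% 2
  }, numeric(1))
}

# exhaustive enumeration of all 4^L words: quantized score (same floor
# grid the calibration uses), exact log-odds score, and background
# probability of every word
oracleEnumerateWords <- function(M, bg, precision) {
  L <- ncol(M)
  mins <- apply(M, 2, min)
  delta <- (sum(apply(M, 2, max)) - sum(mins)) / precision
  Q <- floor(sweep(M, 2, mins, "-") / delta)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  list(
    qscore = sum(mins) + delta *
      apply(words, 1, function(w) sum(Q[cbind(w, seq_len(L))])),
    escore = apply(words, 1, function(w) sum(M[cbind(w, seq_len(L))])),
    prob = apply(words, 1, function(w) prod(bg[w])),
    delta = delta)
}

# P(score >= s) over an enumerated word table
oracleTailProb <- function(scores, probs, s) {
  sum(probs[scores >= s - 1e-9])
}

# smallest achievable score whose tail probability is <= fpr (NA if none),
# grouping words that share a score
oracleMinScoreAtFpr <- function(scores, probs, fpr) {
  agg <- tapply(probs, round(scores, 9), sum)
  u <- as.numeric(names(agg))
  ord <- order(u, decreasing = TRUE)
  tailP <- cumsum(agg[ord])
  ok <- which(tailP <= fpr + 1e-9)
  if (!length(ok)) NA_real_ else u[ord][max(ok)]
}

# derived-locus distances by explicit coordinate concatenation: lay the
# retained acceptor segment along the derived chromosome, append the
# retained donor segment, and measure |feature - TSS| in derived
# coordinates
oracleReconstructDistances <- function(posA, strandA, posB, strandB,
                                       featS0, featE0, tss, donorLen,
                                       accLen) {
  # derived coordinate of acceptor position x (retained segment only)
  if (strandB == "+") {
    if (!(tss < posB)) return(NULL)
    accCoord <- function(x) x                  # [0, posB) kept as-is
    junction <- posB
  } else {
    if (!(tss >= posB)) return(NULL)
    accCoord <- function(x) x - posB           # [posB, accLen) shifts to 0
    junction <- 0
  }
  tssD <- accCoord(tss)
  # donor retained segment mapped so its breakend touches the junction,
  # growing away from the acceptor segment; measure along that axis
  dist <- numeric(0)
  keep <- logical(length(featS0))
  for (i in seq_along(featS0)) {
    if (strandA == "+") {
      if (featS0[i] >= posA) next
      off <- max(0, posA - featE0[i])
    } else {
      if (featE0[i] <= posA) next
      off <- max(0, featS0[i] - posA)
    }
    keep[i] <- TRUE
    dist <- c(dist, abs(tssD - junction) + off)
  }
  list(keep = keep, dist = dist)
}

# all-pairs TSS association oracle
oracleAssociate <- function(mid0, chrom, cls, geneChrom, geneTss, window,
                            wantClass) {
  vapply(seq_along(geneTss), function(i) {
    any(cls == wantClass & chrom == geneChrom[i] &
          abs(mid0 - geneTss[i]) <= window)
  }, logical(1))
}

randomDnaString <- function(n, bg = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}
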