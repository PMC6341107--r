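test_that("PWM construction applies background-proportional pseudocounts", {
  pfm <- matrix(c(10, 0, 0, 0), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- buildPWM(pfm, pseudocountWeight = 1)
  # column total 10 + weight 1; A gets 10 + 0.30
  probs <- pwm@probs
  expect_equal(unname(probs["A", 1]), 10.3 / 11)
  expect_equal(unname(probs["C", 1]), 0.2 / 11)
  expect_equal(sum(probs[, 1]), 1)

  # uniform counts against a uniform background: all log-odds zero
  uni <- buildPWM(matrix(5, 4, 3), pseudocountWeight = 1,
                  background = c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(unname(motifLogOdds(uni)), matrix(0, 4, 3))

  # weight 0 with positive counts is the pure ML estimate
  ml <- buildPWM(matrix(c(3, 1, 0, 0), 4, 1), pseudocountWeight = 0)
  expect_equal(unname(ml@probs["A", 1]), 0.75)
  expect_error(buildPWM(matrix(0, 4, 2), pseudocountWeight = 0),
               "pseudocount")
})

test_that("PFM reader accepts both orientations and labeled rows", {
  m <- toyPfm(L = 6)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  # 4 x L with row labels
  writeLines(c("# comment",
               paste(rownames(m), apply(m, 1, paste, collapse = "\t"),
                     sep = "\t")), f1)
  # L x 4 with header
  writeLines(c(paste(c("A", "C", "G", "T"), collapse = "\t"),
               apply(t(m), 1, paste, collapse = "\t")), f2)
  # bare 4 x L
  writeLines(apply(m, 1, paste, collapse = "\t"), f3)
  expect_equal(readPFM(f1), m, ignore_attr = TRUE)
  expect_equal(readPFM(f2), m, ignore_attr = TRUE)
  expect_equal(readPFM(f3), m, ignore_attr = TRUE)
  expect_equal(rownames(readPFM(f1)), c("A", "C", "G", "T"))
})

test_that("DP threshold calibration matches exhaustive 4^L enumeration for short motifs", {
  for (L in c(4, 6, 8)) {
    pwm <- buildPWM(toyPfm(L = L, seed = L), pseudocountWeight = 1)
    for (fpr in c(1e-2, 1e-3, 1e-4)) {
      cal <- calibrateThreshold(pwm, fpr = fpr, precision = 1e4)
      thr <- motifThreshold(cal)
      enum <- oracleEnumerateWords(motifLogOdds(cal),
                                   motifBackground(cal), 1e4)
      # validity: the threshold's background tail probability is within fpr
      expect_lte(oracleTailProb(enum$qscore, enum$prob, thr), fpr + 1e-9)
      # minimality: the next achievable quantized score below it violates fpr
      below <- enum$qscore[enum$qscore < thr - 1e-9]
      if (length(below))
        expect_gt(oracleTailProb(enum$qscore, enum$prob, max(below)), fpr)
      # the exact-score threshold lies within one quantization band
      thrExact <- oracleMinScoreAtFpr(enum$escore, enum$prob, fpr)
      if (is.na(thrExact)) thrExact <- max(enum$escore) + enum$delta
      expect_lte(abs(thr - thrExact), (L + 1) * enum$delta)
    }
  }
})

test_that("threshold is minimal at fpr 1 and non-decreasing as fpr tightens", {
  pwm <- buildPWM(toyPfm(L = 5, seed = 9))
  t1 <- motifThreshold(calibrateThreshold(pwm, fpr = 1))
  expect_equal(t1, sum(apply(motifLogOdds(pwm), 2, min)), tolerance = 1e-9)
  ts <- vapply(c(0.5, 1e-1, 1e-2, 1e-3, 1e-4),
               function(f) motifThreshold(calibrateThreshold(pwm, fpr = f)),
               numeric(1))
  expect_true(all(diff(ts) >= 0))
})

test_that("scanning finds planted sites, is strand-symmetric and skips N windows", {
  pfmFile <- system.file("extdata", "nbre_consensus_synthetic.pfm",
                         package = "hijackscan")
  pwm <- calibrateThreshold(buildPWM(readPFM(pfmFile)), fpr = 1e-4)
  consensus <- "AAAGGTCA"
  set.seed(14)
  # T-only flanks carry no partial motif matches
  seqStr <- paste0(strrep("T", 50), consensus, strrep("T", 42))
  hits <- scanSequence(seqStr, pwm)
  expect_equal(length(hits), 1L)
  expect_equal(start(hits), 51)
  expect_equal(as.character(strand(hits)), "+")

  # reverse complement: mirrored interval, flipped strand, equal score
  rc <- as.character(reverseComplement(Biostrings::DNAString(seqStr)))
  hitsRc <- scanSequence(rc, pwm)
  expect_equal(length(hitsRc), 1L)
  expect_equal(as.character(strand(hitsRc)), "-")
  expect_equal(hitsRc$score, hits$score)
  expect_equal(start(hitsRc) - 1, nchar(seqStr) - end(hits))

  # case-insensitive; N-containing windows never reported
  expect_equal(length(scanSequence(tolower(seqStr), pwm)), 1L)
  withN <- paste0(strrep("T", 50), "AAAGNTCA", strrep("T", 42))
  expect_length(scanSequence(withN, pwm), 0)
})

test_that("CTCF peaks take the orientation of their best contained hit", {
  peaks <- GRanges("c1", IRanges(c(100, 300, 500), width = 50))
  hits <- GRanges("c1",
                  IRanges(c(110, 310, 320), width = 10),
                  strand = c("+", "+", "-"),
                  score = c(5, 3, 7), pwm = "ctcf")
  out <- annotateCtcfOrientation(peaks, hits)
  expect_equal(as.character(strand(out)), c("+", "-", "*"))
  expect_equal(out$bestHitScore, c(5, 7, NA))
  # adjacent +/- oriented sites form a convergent pair
  pair <- convergentPairs(out)
  expect_equal(length(pair), 1L)
  expect_equal(pair$leftSite, 1L)
  # divergent or tandem neighbors do not
  div <- GRanges("c1", IRanges(c(1, 100), width = 1), strand = c("-", "+"))
  expect_length(convergentPairs(div), 0)
})

test_that("motif enrichment is an exact one-sided binomial of hit fractions", {
  pfmFile <- system.file("extdata", "nbre_consensus_synthetic.pfm",
                         package = "hijackscan")
  pwm <- calibrateThreshold(buildPWM(readPFM(pfmFile)), fpr = 1e-4)
  noHit <- strrep("T", 60)
  withHit <- paste0(strrep("T", 20), "AAAGGTCA", strrep("T", 32))
  # identical hit-free fg and bg: p exactly 1
  r0 <- motifEnrichment(rep(noHit, 10), rep(noHit, 10), pwm)
  expect_equal(r0$pValue, 1)
  # identical fg and bg with intermediate fraction: not significant
  mixed <- c(rep(withHit, 5), rep(noHit, 5))
  rSame <- motifEnrichment(mixed, mixed, pwm)
  expect_gt(rSame$pValue, 0.05)
  # all 50 fg hit-bearing vs background fraction 0.01: astronomically small
  bg <- c(withHit, rep(noHit, 99))
  rBig <- motifEnrichment(rep(withHit, 50), bg, pwm)
  expect_equal(rBig$bgFraction, 0.01)
  expect_lt(rBig$pValue, 1e-90)
  expect_error(motifEnrichment(character(), bg, pwm), "empty")
})
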