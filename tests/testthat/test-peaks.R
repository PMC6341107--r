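test_that("enrichment detection recovers a planted region and respects run maximality", {
  # flat zero track: nothing to call
  flat <- densityTrack(list(c1 = numeric(100)), 32)
  expect_length(detectEnrichedRegions(flat), 0)

  # planted 10x region on a Poisson background
  set.seed(3)
  bg <- rpois(500, 5)
  v <- bg
  v[201:220] <- rpois(20, 50)
  tr <- densityTrack(list(c1 = v), 32)
  pk <- detectEnrichedRegions(tr, foldThreshold = 4, minBins = 3)
  expect_equal(length(pk), 1L)
  b0 <- (start(pk) - 1) / 32
  b1 <- end(pk) / 32 - 1
  expect_lte(abs(b0 - 200), 2)
  expect_lte(abs(b1 - 219), 2)
  expect_gt(pk$signal, 4 * median(bg[bg > 0]))
  expect_true(pk$summit >= start(pk) - 1 & pk$summit <= end(pk))

  # one sub-threshold bin splits a run into two peaks
  v2 <- rep(5, 40)                  # median nonzero bin count 5
  v2[c(10:12, 14:16)] <- 100
  v2[13] <- 19                      # below 4 x median
  tr2 <- densityTrack(list(c1 = v2), 32)
  pk2 <- detectEnrichedRegions(tr2, foldThreshold = 4, minBins = 3)
  expect_equal(length(pk2), 2L)
})

test_that("blacklist filtering removes any peak with >= 1 bp overlap", {
  peaks <- GRanges("c1", IRanges(c(100, 300, 500), width = 50))
  peaks$signal <- c(1, 2, 3)
  bl <- GRanges("c1", IRanges(c(90, 349), c(200, 349)))
  kept <- filterBlacklist(peaks, bl)
  # peak 1 inside blacklist, peak 2 overlaps by exactly 1 bp at 349
  expect_equal(start(kept), 500)
  expect_identical(filterBlacklist(peaks, GRanges()), peaks)
})

test_that("stitching merges at the boundary distance and is transitive and idempotent", {
  mk <- function(s0, e0) {
    gr <- GRanges("c1", IRanges(s0 + 1, e0))
    gr$signal <- rep(1, length(gr))
    gr
  }
  # distance exactly 12,500 merges ...
  m1 <- stitchRegions(mk(c(0, 13000), c(500, 13500)), gap = 12500)
  expect_equal(length(m1), 1L)
  expect_equal(c(start(m1) - 1, end(m1)), c(0, 13500))
  # ... 12,501 does not
  m2 <- stitchRegions(mk(c(0, 13001), c(500, 13501)), gap = 12500)
  expect_equal(length(m2), 2L)

  # pairwise-chained peaks collapse transitively; checked against union-find
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(2:15, 1)
    s0 <- sort(sample(0:200000, n))
    e0 <- s0 + sample(100:5000, n, replace = TRUE)
    pk <- mk(s0, e0)
    st <- stitchRegions(pk, gap = 12500)
    orc <- oracleStitch(s0, e0, 12500)
    expect_equal(cbind(start(st) - 1, end(st)), unname(orc))
    # idempotence on the merged intervals
    st2 <- stitchRegions(st, gap = 12500)
    expect_equal(granges(st2), granges(st))
  }

  # aggregate signal is length-weighted
  pk <- mk(c(0, 1000), c(100, 1200))
  pk$signal <- c(2, 5)
  expect_equal(stitchRegions(pk, gap = 12500)$aggregateSignal,
               2 * 100 + 5 * 200)
})

test_that("super-enhancer flagging follows the max(1, floor(top 5%)) rule with stable ties", {
  mk <- function(n, sig) {
    gr <- GRanges("c1", IRanges(seq(1, by = 20000, length.out = n),
                                width = 1000))
    gr$aggregateSignal <- sig
    gr
  }
  expect_equal(sum(callSuperEnhancers(mk(40, 40:1))$isSuperEnhancer), 2L)
  expect_equal(sum(callSuperEnhancers(mk(10, 10:1))$isSuperEnhancer), 1L)
  # equal-signal tie at the cutoff: the earlier-start region wins
  tie <- mk(10, c(5, rep(1, 9)))
  tie$aggregateSignal[2] <- 5
  # regions 1 and 2 tie; only one slot; region 1 starts earlier
  flagged <- callSuperEnhancers(tie)
  expect_true(flagged$isSuperEnhancer[1])
  expect_false(flagged$isSuperEnhancer[2])
  # ranks are a permutation
  expect_setequal(flagged$rank, 1:10)
})

test_that("union regions equal a per-bp mark-and-sweep oracle", {
  mk <- function(s0, e0) GRanges("c1", IRanges(s0 + 1, e0))
  u <- unionRegions(list(mk(0, 10), mk(5, 20)))
  expect_equal(c(start(u) - 1, end(u)), c(0, 20))
  # adjacent (zero-gap) inputs merge; disjoint inputs pass through
  u2 <- unionRegions(mk(c(0, 10), c(10, 20)))
  expect_equal(length(u2), 1L)
  u3 <- unionRegions(mk(c(0, 100), c(10, 120)))
  expect_equal(length(u3), 2L)
  set.seed(33)
  for (rep in 1:25) {
    nSets <- sample(1:4, 1)
    sets <- lapply(seq_len(nSets), function(i) {
      n <- sample(1:10, 1)
      s0 <- sample(0:900, n)
      mk(s0, s0 + sample(1:150, n, replace = TRUE))
    })
    u <- unionRegions(sets)
    allS <- unlist(lapply(sets, function(g) start(g) - 1))
    allE <- unlist(lapply(sets, end))
    orc <- oracleUnion(allS, allE, 1100)
    expect_equal(cbind(start(u) - 1, end(u)), unname(orc))
  }
})

test_that("differential classification computes the stated log2 ratios and classes", {
  mkTrack <- function(level)
    densityTrack(list(c1 = rep(level, 10)), 32)
  region <- GRanges("c1", IRanges(33, 128))
  cls <- function(t, n, eps)
    classifyDifferential(region, list(mkTrack(t)), mkTrack(n), eps = eps)
  r1 <- cls(8, 2, 0)
  expect_equal(r1$log2Ratio, 2)
  expect_equal(r1$class, "up")
  r2 <- cls(1, 4, 0)
  expect_equal(r2$log2Ratio, -2)
  expect_equal(r2$class, "down")
  r3 <- cls(4, 0, 0.25)
  expect_equal(r3$log2Ratio, log2(17))
  expect_equal(r3$class, "up")
  r4 <- cls(3, 2, 0)
  expect_equal(r4$class, "neutral")
  expect_error(
    classifyDifferential(GRanges("c1", IRanges(1, 1e6)),
                         list(mkTrack(1)), mkTrack(1)),
    "outside")
})

test_that("multi-sample tumor aggregation averages and classes partition the regions", {
  set.seed(8)
  v <- rpois(200, 6)
  normal <- densityTrack(list(c1 = v), 32)
  tumors <- lapply(c(2, 4, 6), function(f)
    densityTrack(list(c1 = v * f), 32))
  regions <- GRanges("c1", IRanges(seq(1, 6000, by = 400), width = 320))
  out <- classifyDifferential(regions, tumors, normal, eps = 0)
  expect_equal(out$meanDensityTumor, out$meanDensityNormal * 4,
               tolerance = 1e-12)
  expect_equal(out$class, rep("up", length(regions)))
  expect_true(all(out$class %in% c("up", "down", "neutral")))
  # planted 4x up and 0.25x down regions recovered exactly on clean densities
  base <- rep(8, 300)
  tum <- base
  tum[21:40] <- 32    # bins of region 2
  tum[61:80] <- 2     # bins of region 4
  tr <- densityTrack(list(c1 = tum), 32)
  no <- densityTrack(list(c1 = base), 32)
  regs <- GRanges("c1", IRanges(32 * c(0, 20, 40, 60, 80) + 1, width = 640))
  got <- classifyDifferential(regs, list(tr), no, eps = 0)
  expect_equal(got$class, c("neutral", "up", "neutral", "down", "neutral"))
})
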