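mkCall <- function(posA, strandA, posB, strandB, quality = 300,
                   support = 30, chromA = "chr4s", chromB = "chr9s") {
  data.frame(chromA = chromA, posA = posA, strandA = strandA,
             chromB = chromB, posB = posB, strandB = strandB,
             quality = quality, support = support,
             stringsAsFactors = FALSE)
}

test_that("translocation filter applies both thresholds inclusively and is idempotent", {
  calls <- rbind(mkCall(1, "+", 2, "-", quality = 255, support = 15),
                 mkCall(1, "+", 2, "-", quality = 254, support = 100),
                 mkCall(1, "+", 2, "-", quality = 300, support = 14))
  kept <- filterTranslocations(calls)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$quality, 255)
  expect_identical(filterTranslocations(kept), kept)
  expect_true(all(rownames(kept) %in% rownames(calls)))
})

test_that("breakpoint classification honors region containment and precedence", {
  loc <- generateLocus(seed = 1)
  ann <- locusAnnotations(loc)
  tss <- acceptorTss(loc)
  win <- ctcfPairWindow(loc)
  intron1 <- donorIntrons(loc)[1]
  triple <- tripleGeneSpan(loc)
  callAt <- function(posA, posB = tss - 300)
    mkCall(posA, "+", posB, "-")
  # inside the FDCSP-like first intron: pattern 3
  p3 <- classifyPattern(callAt(start(intron1) + 100), ann, tss)
  expect_equal(as.character(p3$pattern), "3")
  # between the convergent CTCF pair, outside genes: pattern 1
  p1 <- classifyPattern(callAt(start(win) + 50), ann, tss)
  expect_equal(as.character(p1$pattern), "1")
  # within the triple-gene span: pattern 2
  p2 <- classifyPattern(callAt(start(triple) + 10), ann, tss)
  expect_equal(as.character(p2$pattern), "2")
  # far from all annotations: other
  pOther <- classifyPattern(callAt(10), ann, tss)
  expect_equal(as.character(pOther$pattern), "other")
  # acceptor near-TSS flag is a strict 600-bp upstream window
  expect_true(classifyPattern(callAt(10, tss - 600), ann, tss)$acceptorNearTss)
  expect_false(classifyPattern(callAt(10, tss - 601), ann, tss)$acceptorNearTss)
  expect_false(classifyPattern(callAt(10, tss), ann, tss)$acceptorNearTss)
  # a missing annotation class is reported by name
  expect_error(classifyPattern(callAt(10), ann[ann$class != "intron"], tss),
               "intron")
})

test_that("a planted 4/10/1 cohort with noise is fully recovered", {
  loc <- generateLocus(seed = 1)
  tx <- generateTranslocations(loc, c(rep(1, 4), rep(2, 10), 3),
                               nNoise = 5, seed = 11)
  truth <- attr(tx, "truth")
  kept <- filterTranslocations(tx)
  # exactly the planted noise fails the filter
  expect_setequal(kept$id, truth$id[truth$passesFilter])
  expect_equal(nrow(tx) - nrow(kept), 5L)
  pc <- classifyPattern(kept, locusAnnotations(loc), acceptorTss(loc))
  expect_equal(as.character(pc$pattern),
               truth$pattern[truth$passesFilter])
  expect_equal(unname(table(pc$pattern)[c("1", "2", "3")]),
               c(4L, 10L, 1L), ignore_attr = TRUE)
})

test_that("derived-locus distances follow breakend arithmetic", {
  tss <- 500000
  # acceptor breakend 600 bp upstream, right segment retained (has TSS);
  # donor breakend with an enhancer whose near edge is 90 kb left of it
  enh <- GRanges("chr4s", IRanges(309001, 311000))  # 0-based [309000,311000)
  names(enh) <- "E1"
  call <- mkCall(401000, "+", tss - 600, "-")
  rl <- reconstructDerivedLocus(call, enh, tss)
  expect_equal(rl$junctionDistance, 600)
  expect_equal(rl$features$distanceToTss, 90000 + 600)
  # a feature on the non-retained side is absent
  lost <- GRanges("chr4s", IRanges(450001, 452000))
  names(lost) <- "L1"
  rl2 <- reconstructDerivedLocus(call, c(enh, lost), tss)
  expect_equal(rl2$features$name, "E1")
  # TSS must land on the derived chromosome
  expect_error(
    reconstructDerivedLocus(mkCall(1000, "+", tss - 600, "+"), enh, tss),
    "TSS not on derived chromosome")
})

test_that("mirror-symmetric fusions yield identical distance lists", {
  set.seed(19)
  donorLen <- 1e6
  for (rep in 1:100) {
    n <- sample(1:6, 1)
    s0 <- sample(0:(donorLen - 5000), n)
    e0 <- s0 + sample(500:4000, n, replace = TRUE)
    posA <- sample(0:(donorLen - 1), 1)
    tss <- 500000
    off <- sample(1:5000, 1)
    feats <- GRanges("chr4s", IRanges(s0 + 1, e0))
    names(feats) <- sprintf("f%02d", seq_len(n))
    fwd <- reconstructDerivedLocus(mkCall(posA, "+", tss - off, "-"),
                                   feats, tss)
    # mirrored donor: x -> donorLen - x flips retained side to "-"
    mfeats <- GRanges("chr4s", IRanges(donorLen - e0 + 1, donorLen - s0))
    names(mfeats) <- names(feats)
    revv <- reconstructDerivedLocus(
      mkCall(donorLen - posA, "-", tss - off, "-"), mfeats, tss)
    expect_equal(fwd$features$distanceToTss, revv$features$distanceToTss)
    expect_equal(fwd$features$name, revv$features$name)
    # distances are non-negative and ordered outward from the TSS
    expect_true(all(fwd$features$distanceToTss >= fwd$junctionDistance))
    expect_false(is.unsorted(fwd$features$distanceToTss))
  }
})

test_that("reconstruction agrees with an independent coordinate-concatenation oracle", {
  set.seed(23)
  donorLen <- 1e6; accLen <- 1e6
  for (rep in 1:100) {
    n <- sample(1:6, 1)
    s0 <- sample(0:(donorLen - 5000), n)
    e0 <- s0 + sample(500:4000, n, replace = TRUE)
    posA <- sample(0:(donorLen - 1), 1)
    strandA <- sample(c("+", "-"), 1)
    tss <- sample(200000:800000, 1)
    posB <- tss - sample(1:10000, 1)
    feats <- GRanges("chr4s", IRanges(s0 + 1, e0))
    names(feats) <- sprintf("f%02d", seq_len(n))
    call <- mkCall(posA, strandA, posB, "-")
    got <- reconstructDerivedLocus(call, feats, tss)
    orc <- oracleReconstructDistances(posA, strandA, posB, "-",
                                      s0, e0, tss, donorLen, accLen)
    expect_equal(sort(got$features$distanceToTss), sort(orc$dist))
    expect_setequal(got$features$name, names(feats)[orc$keep])
  }
})

test_that("insulator separation requires the CTCF site and TSS on opposite sides", {
  tss <- 500000
  sep <- insulatorSeparationCheck(mkCall(1, "+", tss - 600, "-"),
                                  tss - 13500, tss)
  expect_true(sep)
  expect_false(insulatorSeparationCheck(mkCall(1, "+", tss - 600, "-"),
                                        tss - 400, tss))
  expect_false(insulatorSeparationCheck(mkCall(1, "+", tss - 600, "-"),
                                        numeric(), tss))
})
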