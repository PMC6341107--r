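# Synthetic-data generators. Every input the pipeline consumes can be
# generated from a LocusModel with planted ground truth: ChIP tags with
# Poisson-like background and planted fold enrichment, multi-sample TAD
# boundary calls with jitter and dropout, translocations of the three
# breakpoint patterns plus sub-threshold noise, negative-binomial counts
# with planted differential genes, and binomial FISH tallies.
#
# The defaults model the studied disease configuration: a ~340-kb donor
# gene cluster of abundantly expressed salivary-gland-type genes
# (FDCSP-like with introns; a STATH/HTN3/HTN1-like triple span), a
# convergent CTCF pair bounding a sub-TAD, clustered strong enhancers, and
# an acceptor proto-oncogene TSS with a CTCF insulator site 13.5 kb
# upstream. Chromosomes are named chr4s/chr9s ("s" = synthetic) to avoid
# confusion with real genome builds.

#' Configuration for the synthetic locus model
#'
#' @param chromLengths named lengths of donor and acceptor chromosomes
#'   (bp), default 1 Mb each.
#' @param nEnhancers number of planted donor enhancers, default 5.
#' @param nCtcfSites number of donor CTCF sites (>= 2; the first two form
#'   the convergent pair), default 6.
#' @param enhancerWidth enhancer width in bp, default 2000.
#' @param enhancerFoldRange range of planted tag-rate folds, default
#'   c(5, 15).
#' @param clusterSpan 0-based span of the donor gene/enhancer cluster,
#'   default c(300000, 640000) (~340 kb).
#' @param acceptorTss 0-based acceptor TSS position, default 500000.
#' @param acceptorCtcfOffset distance of the acceptor CTCF site upstream
#'   of the TSS, default 13500 bp.
#' @param positionJitter maximal seeded jitter of enhancer anchors (bp),
#'   default 500.
#' @return named list of configuration values
#' @export
locusConfig <- function(chromLengths = c(chr4s = 1e6, chr9s = 1e6),
                        nEnhancers = 5, nCtcfSites = 6,
                        enhancerWidth = 2000,
                        enhancerFoldRange = c(5, 15),
                        clusterSpan = c(300000, 640000),
                        acceptorTss = 500000,
                        acceptorCtcfOffset = 13500,
                        positionJitter = 500) {
  list(chromLengths = chromLengths, nEnhancers = nEnhancers,
       nCtcfSites = nCtcfSites, enhancerWidth = enhancerWidth,
       enhancerFoldRange = enhancerFoldRange, clusterSpan = clusterSpan,
       acceptorTss = acceptorTss, acceptorCtcfOffset = acceptorCtcfOffset,
       positionJitter = positionJitter)
}

#' Generate the two-locus enhancer-hijacking model
#'
#' Builds a [LocusModel-class] from a configuration: fixed donor gene
#' skeleton (an FDCSP-like gene with introns, a triple-gene span, flanking
#' cluster genes), a convergent CTCF pair whose between-window defines
#' breakpoint pattern 1, and seeded placement of the requested number of
#' enhancers and additional CTCF sites. Deterministic under \code{seed}.
#'
#' @param config list from [locusConfig()].
#' @param seed integer seed.
#' @return a validated [LocusModel-class]
#' @export
generateLocus <- function(config = locusConfig(), seed = 1L) {
  donorChrom <- names(config$chromLengths)[1]
  acceptorChrom <- names(config$chromLengths)[2]
  donorLen <- config$chromLengths[[1]]
  accLen <- config$chromLengths[[2]]
  span <- config$clusterSpan
  if (span[2] > donorLen || span[1] < 0)
    stop("cluster span exceeds donor chromosome length")
  if (config$acceptorTss >= accLen)
    stop("acceptor TSS exceeds acceptor chromosome length")
  if (config$nCtcfSites < 2L)
    stop("at least 2 CTCF sites are needed for the convergent pair")
  scale <- donorLen / 1e6   # gene skeleton scales with donor length
  at <- function(x) round(x * scale)
  geneDef <- data.frame(
    gene_id = c("SCPP1_like", "FDCSP_like", "SCPP2_like", "SCPP3_like",
                "STATH_like", "HTN3_like", "HTN1_like", "SCPP4_like"),
    s0 = at(c(300000, 320000, 350000, 370000, 400000, 420000, 440000,
              620000)),
    e0 = at(c(310000, 340000, 360000, 380000, 412000, 432000, 452000,
              640000)),
    triple = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  genes <- GRanges(donorChrom, IRanges(geneDef$s0 + 1, geneDef$e0),
                   gene_id = geneDef$gene_id,
                   in_triple_span = geneDef$triple)
  # FDCSP-like intron structure: exons at both ends and mid-gene
  fd <- geneDef[geneDef$gene_id == "FDCSP_like", ]
  introns <- GRanges(donorChrom,
                     IRanges(at(c(322000, 332000)) + 1,
                             at(c(330000, 338000))),
                     gene_id = "FDCSP_like", intron_number = 1:2)
  pairFwd <- at(470000); pairRev <- at(500000)
  extraAnchors <- at(c(150000, 250000, 550000, 700000, 850000, 950000,
                       50000, 600000))
  nExtra <- config$nCtcfSites - 2L
  if (nExtra > length(extraAnchors))
    stop("too many CTCF sites requested for the donor layout")
  ctcfPos <- c(pairFwd, pairRev, extraAnchors[seq_len(nExtra)])
  ctcfStr <- c("+", "-",
               rep(c("-", "+"), length.out = nExtra))  # extras non-convergent
  ord <- order(ctcfPos)
  ctcf <- GRanges(donorChrom, IRanges(ctcfPos[ord] + 1, width = 1),
                  strand = ctcfStr[ord])
  model <- withSeed(seed, {
    n <- config$nEnhancers
    w <- config$enhancerWidth
    pad <- max(w, 10000)
    anchors <- if (n == 1L) round(mean(span)) else
      round(seq(span[1] + pad, span[2] - pad - w, length.out = n))
    jit <- if (config$positionJitter > 0)
      sample(-config$positionJitter:config$positionJitter, n, replace = TRUE)
    else rep(0L, n)
    s0 <- pmax(0, pmin(anchors + jit, donorLen - w))
    folds <- round(runif(n, config$enhancerFoldRange[1],
                         config$enhancerFoldRange[2]), 1)
    enh <- GRanges(donorChrom, IRanges(s0 + 1, width = w),
                   fold = folds,
                   name = sprintf("enhancer_%02d", seq_len(n)))
    if (max(end(enh)) > donorLen)
      stop("enhancer interval exceeds donor chromosome length")
    new("LocusModel",
        donorChrom = donorChrom, acceptorChrom = acceptorChrom,
        chromLengths = setNames(as.numeric(config$chromLengths),
                                names(config$chromLengths)),
        donorEnhancers = enh, donorCtcfSites = ctcf,
        donorGenes = genes, donorIntrons = introns,
        acceptorTss = as.numeric(config$acceptorTss),
        acceptorCtcfSite = as.numeric(config$acceptorTss -
                                        config$acceptorCtcfOffset))
  })
  validObject(model)
  model
}

#' Planted TAD boundary positions of a locus model
#'
#' The ground-truth boundary set used by [generateBoundaryCalls()]: on the
#' donor chromosome the convergent CTCF pair positions (sub-TAD borders)
#' plus two flanking domain boundaries; on the acceptor chromosome a
#' boundary at the TSS-containing domain edge plus flanks.
#'
#' @param locus a [LocusModel-class]
#' @return data.frame with columns \code{chrom} and \code{pos} (0-based)
#' @export
plantedBoundaries <- function(locus) {
  stopifnot(is(locus, "LocusModel"))
  ctcf <- sort(locus@donorCtcfSites, ignore.strand = TRUE)
  s <- as.character(strand(ctcf))
  i <- which(s[-length(s)] == "+" & s[-1] == "-")[1]
  donorLen <- locus@chromLengths[[locus@donorChrom]]
  accLen <- locus@chromLengths[[locus@acceptorChrom]]
  rbind(
    data.frame(chrom = locus@donorChrom,
               pos = c(round(donorLen * 0.1),
                       start(ctcf)[i] - 1, start(ctcf)[i + 1] - 1,
                       round(donorLen * 0.8))),
    data.frame(chrom = locus@acceptorChrom,
               pos = c(round(accLen * 0.25), locus@acceptorTss,
                       round(accLen * 0.75))))
}

#' Simulate ChIP-seq tag tables with planted enrichment
#'
#' Draws \code{depth} tag positions from a per-bp rate that is uniform
#' background multiplied, inside each planted enriched interval, by its
#' fold. Fragment centers are converted to 5' tag positions with the real
#' ChIP shift: forward tags sit half a fragment length left of the center,
#' reverse tags right. Under the tumor condition, tumor-only regions
#' (by default a strong peak directly upstream of the acceptor TSS,
#' emulating acquired proto-oncogene activation) are added to the planted
#' set.
#'
#' @param locus a [LocusModel-class].
#' @param condition "normal" or "tumor".
#' @param depth total number of tags to draw (> 0).
#' @param seed integer seed; same seed gives a byte-identical table.
#' @param fragmentLength fragment length used for the strand shift,
#'   default 200.
#' @param enriched GRanges of enriched intervals with a \code{fold}
#'   column; default the locus' donor enhancers.
#' @param tumorRegions GRanges with \code{fold}, added under the tumor
#'   condition; default a 2-kb fold-8 region directly upstream of the
#'   acceptor TSS.
#' @return data.frame with columns \code{chrom}, \code{pos} (0-based 5'
#'   position) and \code{strand}.
#' @export
generateChipTags <- function(locus, condition = c("normal", "tumor"),
                             depth = 20000, seed = 1L,
                             fragmentLength = 200,
                             enriched = NULL, tumorRegions = NULL) {
  stopifnot(is(locus, "LocusModel"))
  condition <- match.arg(condition)
  if (depth < 1) stop("depth must be at least 1")
  if (is.null(enriched)) enriched <- locus@donorEnhancers
  if (condition == "tumor") {
    if (is.null(tumorRegions)) {
      tss0 <- locus@acceptorTss
      tumorRegions <- GRanges(locus@acceptorChrom,
                              IRanges(tss0 - 2000 + 1, tss0), fold = 8)
    }
    enriched <- suppressWarnings(c(enriched, tumorRegions))
  }
  lens <- locus@chromLengths
  # sampling components: uniform background per chromosome, plus the extra
  # (fold - 1) mass of each enriched interval
  compChrom <- c(names(lens), as.character(seqnames(enriched)))
  compStart0 <- c(rep(0, length(lens)), start(enriched) - 1)
  compEnd0 <- c(unname(lens), end(enriched))
  compW <- c(unname(lens),
             (enriched$fold - 1) * width(enriched))
  withSeed(seed, {
    comp <- sample.int(length(compW), depth, replace = TRUE,
                       prob = compW / sum(compW))
    center <- floor(compStart0[comp] +
                      runif(depth) * (compEnd0[comp] - compStart0[comp]))
    strand <- ifelse(runif(depth) < 0.5, "+", "-")
    shift <- fragmentLength %/% 2
    chromLen <- lens[compChrom[comp]]
    pos <- ifelse(strand == "+", center - shift, center + shift)
    pos <- pmax(0, pmin(pos, chromLen - 1))
    data.frame(chrom = compChrom[comp], pos = as.integer(pos),
               strand = strand, stringsAsFactors = FALSE)
  })
}

#' Simulate multi-sample TAD boundary call sets
#'
#' Each sample carries the planted boundary positions of the locus
#' (see [plantedBoundaries()]) perturbed by integer Gaussian jitter, with
#' each boundary independently dropped at \code{dropRate}.
#'
#' @param locus a [LocusModel-class].
#' @param nSamples number of samples, default 29 (the published Hi-C map
#'   collection size this emulates).
#' @param jitterSd standard deviation of the integer position jitter (bp).
#' @param dropRate per-boundary dropout probability.
#' @param seed integer seed.
#' @return named list of GRanges (1-bp boundary positions), with the
#'   planted truth attached as \code{attr(, "truth")}.
#' @export
generateBoundaryCalls <- function(locus, nSamples = 29, jitterSd = 0,
                                  dropRate = 0, seed = 1L) {
  stopifnot(is(locus, "LocusModel"), nSamples >= 1)
  truth <- plantedBoundaries(locus)
  lens <- locus@chromLengths
  sets <- withSeed(seed, {
    lapply(seq_len(nSamples), function(i) {
      keep <- runif(nrow(truth)) >= dropRate
      df <- truth[keep, , drop = FALSE]
      if (!nrow(df)) return(GRanges())
      jit <- if (jitterSd > 0) round(rnorm(nrow(df), 0, jitterSd)) else 0
      pos <- pmax(0, pmin(df$pos + jit, lens[df$chrom] - 1))
      GRanges(df$chrom, IRanges(pos + 1, width = 1))
    })
  })
  names(sets) <- sprintf("sample_%02d", seq_len(nSamples))
  attr(sets, "truth") <- truth
  sets
}

#' Simulate translocation calls of the three breakpoint patterns
#'
#' For every requested pattern a call is emitted whose donor breakend
#' falls in the pattern's defining region (1: between the convergent CTCF
#' pair, outside genes; 2: within the triple-gene span; 3: within the
#' first intron of the FDCSP-like gene) and whose acceptor breakend falls
#' within \code{upstreamWindow} bp directly upstream of the acceptor TSS
#' with probability \code{pUpstream}. All pattern calls pass the standard
#' quality/support filter; each of the \code{nNoise} noise calls fails it
#' on exactly one attribute (quality < 255 or support < 15).
#'
#' @param locus a [LocusModel-class].
#' @param patterns vector over \{1, 2, 3\}, one call per element (repeats
#'   allowed), e.g. \code{c(rep(1, 4), rep(2, 10), 3)} for the cohort the
#'   model emulates.
#' @param nNoise number of sub-threshold noise calls.
#' @param pUpstream probability the acceptor breakend lands in the
#'   upstream window, default 1.
#' @param upstreamWindow bp directly upstream of the TSS, default 600.
#' @param seed integer seed.
#' @return data.frame with columns \code{chromA}, \code{posA},
#'   \code{strandA}, \code{chromB}, \code{posB}, \code{strandB},
#'   \code{quality}, \code{support}, \code{id}; planted truth (id,
#'   pattern, passesFilter) attached as \code{attr(, "truth")}.
#' @export
generateTranslocations <- function(locus, patterns = c(1, 2, 3),
                                   nNoise = 0, pUpstream = 1,
                                   upstreamWindow = 600, seed = 1L) {
  stopifnot(is(locus, "LocusModel"))
  if (length(patterns) && !all(patterns %in% 1:3))
    stop("unknown pattern id: ",
         paste(setdiff(patterns, 1:3), collapse = ", "))
  win <- ctcfPairWindow(locus)
  triple <- tripleGeneSpan(locus)
  intron1 <- locus@donorIntrons[locus@donorIntrons$gene_id == "FDCSP_like" &
                                  locus@donorIntrons$intron_number == 1]
  regionFor <- function(p) switch(as.character(p),
                                  "1" = win, "2" = triple, "3" = intron1)
  tss0 <- locus@acceptorTss
  lens <- locus@chromLengths
  withSeed(seed, {
    rows <- lapply(seq_along(patterns), function(k) {
      r <- regionFor(patterns[k])
      posA <- (start(r) - 1) + sample.int(width(r), 1) - 1L
      upstream <- runif(1) < pUpstream
      off <- if (upstream) sample.int(upstreamWindow, 1) else
        upstreamWindow + sample.int(50000, 1)
      data.frame(chromA = locus@donorChrom, posA = posA,
                 strandA = if (patterns[k] == 2 && runif(1) < 0.5) "-"
                           else "+",
                 chromB = locus@acceptorChrom, posB = tss0 - off,
                 strandB = "-",
                 quality = 255 + rpois(1, 20),
                 support = 15 + rpois(1, 25),
                 stringsAsFactors = FALSE)
    })
    noise <- lapply(seq_len(nNoise), function(k) {
      failQuality <- runif(1) < 0.5
      data.frame(chromA = locus@donorChrom,
                 posA = sample.int(lens[[locus@donorChrom]], 1) - 1L,
                 strandA = sample(c("+", "-"), 1),
                 chromB = locus@acceptorChrom,
                 posB = sample.int(lens[[locus@acceptorChrom]], 1) - 1L,
                 strandB = sample(c("+", "-"), 1),
                 quality = if (failQuality) sample.int(255, 1) - 1L else
                   255 + rpois(1, 20),
                 support = if (failQuality) 15 + rpois(1, 25) else
                   sample.int(15, 1) - 1L,
                 stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, c(rows, noise))
    calls$id <- sprintf("tx_%02d", seq_len(nrow(calls)))
    truth <- data.frame(
      id = calls$id,
      pattern = c(as.character(patterns), rep("noise", nNoise)),
      passesFilter = c(rep(TRUE, length(patterns)), rep(FALSE, nNoise)),
      stringsAsFactors = FALSE)
    attr(calls, "truth") <- truth
    calls
  })
}

#' Simulate read counts and break-apart FISH tallies
#'
#' Counts are negative binomial around per-gene baselines; the planted
#' differentially expressed genes (the acceptor proto-oncogene analogue
#' \code{NR4A3_like} and a hijack-target analogue \code{ENHTARGET_like})
#' have their mean multiplied by \code{deFold} in tumor samples. The gene
#' table includes genes on excluded chromosomes (chrX, chrY, chrMT) and of
#' excluded biotypes (rRNA, tRNA) to exercise library-size exclusion.
#' FISH tallies are binomial draws of aberrant cells out of
#' \code{nCells} per case, with per-case aberrant-cell probability above
#' or below the 20% scoring cutoff according to the planted status.
#'
#' @param locus a [LocusModel-class].
#' @param nTumor,nNormal numbers of tumor and normal RNA samples.
#' @param seed integer seed.
#' @param nBackgroundGenes count of neutral background genes, default 50.
#' @param deFold planted tumor fold change of the DE genes, default 4.
#' @param dispersion negative-binomial dispersion, default 0.05.
#' @param fishCases data.frame with columns \code{case_id}, \code{group},
#'   \code{planted_positive}; default a 20-case positive-entity / 20-case
#'   negative-entity cohort.
#' @param pAberrantPos,pAberrantNeg aberrant-cell probabilities for
#'   planted positive / negative cases, defaults 0.6 and 0.02.
#' @param nCells inspected cells per case, default 50.
#' @return list with \code{counts} (genes x samples), \code{geneModels},
#'   \code{fish} (case_id, group, n_cells, n_aberrant) and \code{truth}.
#' @export
generateCountsAndFish <- function(locus, nTumor = 10, nNormal = 3,
                                  seed = 1L, nBackgroundGenes = 50,
                                  deFold = 4, dispersion = 0.05,
                                  fishCases = NULL,
                                  pAberrantPos = 0.6, pAberrantNeg = 0.02,
                                  nCells = 50) {
  stopifnot(is(locus, "LocusModel"), nTumor >= 1, nNormal >= 1)
  if (is.null(fishCases))
    fishCases <- data.frame(
      case_id = sprintf("case_%02d", 1:40),
      group = rep(c("entityA", "entityB"), each = 20),
      planted_positive = rep(c(TRUE, FALSE), each = 20),
      stringsAsFactors = FALSE)
  dg <- locus@donorGenes
  withSeed(seed, {
    bg <- data.frame(
      gene_id = sprintf("gene_%03d", seq_len(nBackgroundGenes)),
      chrom = sample(c("chr1", "chr2", "chr3"), nBackgroundGenes, TRUE),
      length = sample(500:5000, nBackgroundGenes, TRUE),
      biotype = "protein_coding",
      tss = sample.int(1e6, nBackgroundGenes),
      baseline = exp(rnorm(nBackgroundGenes, log(500), 0.7)),
      deGene = FALSE, stringsAsFactors = FALSE)
    donor <- data.frame(
      gene_id = dg$gene_id, chrom = locus@donorChrom,
      length = pmin(width(dg), 8000), biotype = "protein_coding",
      tss = start(dg) - 1,
      baseline = exp(rnorm(length(dg), log(2000), 0.3)),
      deGene = FALSE, stringsAsFactors = FALSE)
    special <- data.frame(
      gene_id = c("NR4A3_like", "ENHTARGET_like",
                  "chrX_gene", "chrX_gene2", "chrY_gene", "chrMT_gene",
                  "rRNA_gene", "tRNA_gene"),
      chrom = c(locus@acceptorChrom, locus@acceptorChrom,
                "chrX", "chrX", "chrY", "chrMT", "chr1", "chr2"),
      length = c(3000, 2500, 1500, 2000, 1200, 800, 160, 75),
      biotype = c(rep("protein_coding", 6), "rRNA", "tRNA"),
      tss = c(locus@acceptorTss, locus@acceptorTss + 200000,
              1e5, 2e5, 1e5, 2e3, 3e5, 4e5),
      baseline = c(400, 300, 600, 300, 200, 5000, 20000, 8000),
      deGene = c(TRUE, TRUE, rep(FALSE, 6)),
      stringsAsFactors = FALSE)
    genes <- rbind(special, donor, bg)
    samples <- c(sprintf("tumor_%02d", seq_len(nTumor)),
                 sprintf("normal_%02d", seq_len(nNormal)))
    isTumor <- rep(c(TRUE, FALSE), c(nTumor, nNormal))
    mu <- outer(genes$baseline, rep(1, length(samples)))
    mu[genes$deGene, isTumor] <- mu[genes$deGene, isTumor] * deFold
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = nrow(genes),
                     dimnames = list(genes$gene_id, samples))
    pAb <- ifelse(fishCases$planted_positive, pAberrantPos, pAberrantNeg)
    fish <- data.frame(case_id = fishCases$case_id,
                       group = fishCases$group,
                       n_cells = nCells,
                       n_aberrant = rbinom(nrow(fishCases), nCells, pAb),
                       stringsAsFactors = FALSE)
    geneModels <- genes[, c("gene_id", "chrom", "length", "biotype",
                            "tss")]
    geneModels$strand <- "+"
    list(counts = counts, geneModels = geneModels, fish = fish,
         truth = list(deGenes = genes$gene_id[genes$deGene],
                      deFold = deFold,
                      fishStatus = setNames(fishCases$planted_positive,
                                            fishCases$case_id)))
  })
}
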