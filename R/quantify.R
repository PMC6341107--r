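# Expression quantification (FPKM/TPM with library-size exclusions),
# peak-to-gene association by TSS window, and break-apart FISH / IHC
# cohort scoring.

#' Compute FPKM and TPM with library-size exclusions
#'
#' Library size per sample is the sum of counts over genes NOT on the
#' excluded chromosomes (sex chromosomes and the mitochondrial genome) and
#' NOT of the excluded biotypes (rRNA, tRNA), which would otherwise bias
#' library-size estimation. Excluded genes still receive FPKM/TPM values,
#' computed against the included-only library size.
#' FPKM = count / (length/1e3) / (libSize/1e6); TPM_i = rate_i /
#' sum(included rate_j) * 1e6 with rate = count / length.
#'
#' @param counts genes x samples numeric matrix (row names = gene ids).
#' @param geneModels data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{length} (exonic bp > 0) and \code{biotype}; every counted gene
#'   must have a model.
#' @param excludeChroms chromosome names omitted from library size.
#' @param excludeBiotypes biotypes omitted from library size.
#' @return list with matrices \code{fpkm} and \code{tpm}, the logical
#'   \code{included} vector and \code{librarySize} per sample.
#' @export
computeFpkmTpm <- function(counts, geneModels,
                           excludeChroms = c("chrX", "chrY", "chrM",
                                             "chrMT", "X", "Y", "MT"),
                           excludeBiotypes = c("rRNA", "tRNA")) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  stopifnot(all(c("gene_id", "chrom", "length", "biotype") %in%
                  names(geneModels)))
  gm <- geneModels[match(rownames(counts), geneModels$gene_id), ]
  if (anyNA(gm$gene_id))
    stop("gene without a model: ",
         paste(head(rownames(counts)[is.na(gm$gene_id)]), collapse = ", "))
  if (any(gm$length <= 0)) stop("gene lengths must be positive")
  included <- !(gm$chrom %in% excludeChroms) &
    !(gm$biotype %in% excludeBiotypes)
  libSize <- colSums(counts[included, , drop = FALSE])
  if (any(libSize == 0)) stop("zero library size after exclusions")
  fpkm <- sweep(counts / (gm$length / 1e3), 2, libSize / 1e6, "/")
  rate <- counts / gm$length
  rateSum <- colSums(rate[included, , drop = FALSE])
  tpm <- sweep(rate, 2, rateSum, "/") * 1e6
  list(fpkm = fpkm, tpm = tpm, included = setNames(included,
                                                   rownames(counts)),
       librarySize = libSize)
}

#' Per-gene log2 fold change of mean TPM (descriptive only)
#'
#' A descriptive tumor-vs-normal log2 ratio of mean TPM per gene; proper
#' differential testing is left to dedicated count-model tools.
#'
#' @param tpm genes x samples TPM matrix.
#' @param tumorSamples,normalSamples column names or indices.
#' @param eps pseudocount in TPM units, default 1.
#' @return named numeric vector of log2 fold changes
#' @export
tpmLog2FoldChange <- function(tpm, tumorSamples, normalSamples, eps = 1) {
  t <- rowMeans(tpm[, tumorSamples, drop = FALSE])
  n <- rowMeans(tpm[, normalSamples, drop = FALSE])
  setNames(log2((t + eps) / (n + eps)), rownames(tpm))
}

#' Associate differential regions with genes by TSS proximity
#'
#' A gene is flagged for a differential class (up / down) when at least one
#' region of that class has its midpoint within \code{window} bp of the
#' gene's TSS. Reports per-gene flags and the fraction of flagged genes per
#' class.
#'
#' @param diffRegions GRanges with a \code{class} metadata column (see
#'   [classifyDifferential()]).
#' @param geneModels data.frame with columns \code{gene_id}, \code{chrom}
#'   and \code{tss} (0-based).
#' @param window TSS window in bp, default 50000.
#' @return list with \code{genes} (data.frame gene_id, upAssociated,
#'   downAssociated) and \code{fractions} (named numeric).
#' @export
associatePeaksToGenes <- function(diffRegions, geneModels, window = 50000) {
  stopifnot(is(diffRegions, "GRanges"), window >= 0,
            all(c("gene_id", "chrom", "tss") %in% names(geneModels)))
  mid <- (start(diffRegions) - 1 + end(diffRegions)) / 2  # 0-based midpoint
  chrom <- as.character(seqnames(diffRegions))
  cls <- diffRegions$class
  flag <- function(gene, wantClass) {
    sel <- cls == wantClass & chrom == gene$chrom &
      abs(mid - gene$tss) <= window
    any(sel)
  }
  up <- logical(nrow(geneModels))
  down <- logical(nrow(geneModels))
  for (i in seq_len(nrow(geneModels))) {
    up[i] <- flag(geneModels[i, ], "up")
    down[i] <- flag(geneModels[i, ], "down")
  }
  list(genes = data.frame(gene_id = geneModels$gene_id,
                          upAssociated = up, downAssociated = down,
                          stringsAsFactors = FALSE),
       fractions = c(up = mean(up), down = mean(down)))
}

#' Score a break-apart FISH case
#'
#' A case is called rearranged when the fraction of tumor cells with
#' aberrant (split or isolated) signals strictly exceeds \code{cutoff}
#' (default >20% of the 50 inspected cells).
#'
#' @param nAberrant number of cells with aberrant signals.
#' @param nCells number of inspected cells (default 50; must be > 0).
#' @param cutoff aberrant-cell fraction cutoff, default 0.20 (strict).
#' @return logical: rearranged or not (vectorized over cases)
#' @export
scoreFishCase <- function(nAberrant, nCells = 50, cutoff = 0.20) {
  if (any(nCells == 0)) stop("nCells must be positive")
  if (any(nAberrant < 0 | nAberrant > nCells))
    stop("nAberrant must be between 0 and nCells")
  nAberrant / nCells > cutoff
}

#' Summarize positive calls per cohort group
#'
#' Per group: number of positive cases, number of evaluable cases, and the
#' percentage positive rounded half away from zero to an integer.
#' Non-evaluable records are excluded from denominators; groups with no
#' evaluable case are omitted with a warning.
#'
#' @param status logical vector of per-case calls (NA = non-evaluable).
#' @param group factor or character of group labels, same length.
#' @param evaluable optional logical; records with FALSE (or NA status)
#'   are excluded from denominators.
#' @return data.frame with columns \code{group}, \code{positive},
#'   \code{evaluable}, \code{percent}.
#' @export
cohortSummary <- function(status, group, evaluable = NULL) {
  stopifnot(length(status) == length(group))
  if (is.null(evaluable)) evaluable <- !is.na(status)
  else evaluable <- evaluable & !is.na(status)
  groups <- unique(as.character(group))
  rows <- lapply(groups, function(g) {
    sel <- as.character(group) == g & evaluable
    n <- sum(sel)
    if (n == 0L) {
      warning("group with no evaluable case omitted: ", g)
      return(NULL)
    }
    pos <- sum(status[sel])
    data.frame(group = g, positive = pos, evaluable = n,
               percent = as.integer(roundHalfUp(100 * pos / n)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), positive = integer(),
                      evaluable = integer(), percent = integer())
  rownames(out) <- NULL
  out
}
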