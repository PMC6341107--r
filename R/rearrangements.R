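# Translocation handling: quality/support filtering, three-pattern
# breakpoint classification against locus annotations, derived-chromosome
# reconstruction with feature-to-TSS distances, and the insulator
# separation check.
#
# Breakend convention (documented in the SV table header): for each
# breakend, strand "+" means the segment to the LEFT of pos is retained on
# the derived chromosome, "-" means the segment to the RIGHT is retained.
# Positions are 0-based in tables.

#' Filter translocation calls on quality and read support
#'
#' Keeps calls with quality score at least \code{minQuality} AND read
#' support of at least \code{minSupport} (defaults 255 and 15, the hybrid
#' capture pipeline's cutoffs). The filter is a pure predicate: output is a
#' subset of input and the operation is idempotent.
#'
#' @param calls translocation data.frame with columns \code{quality} and
#'   \code{support} (see [generateTranslocations()] / [readSvTable()]).
#' @param minQuality minimum quality score, default 255.
#' @param minSupport minimum supporting reads, default 15.
#' @return the retained rows of \code{calls}
#' @export
filterTranslocations <- function(calls, minQuality = 255, minSupport = 15) {
  stopifnot(is.data.frame(calls),
            all(c("quality", "support") %in% names(calls)))
  calls[calls$quality >= minQuality & calls$support >= minSupport, ,
        drop = FALSE]
}

#' Classify donor breakpoints into the three rearrangement patterns
#'
#' Assigns each call's donor-side breakend (breakend A) one of three
#' recurrent patterns: pattern 3 when it falls within an annotated intron
#' (intragenic, the most specific), pattern 1 when it falls in the window
#' between a convergent CTCF pair and outside any gene, pattern 2 when it
#' falls within the span of the three most abundantly expressed donor
#' genes; anything else is "other". Precedence 3 > 1 > 2 (most specific
#' containment wins). The acceptor-side breakend is separately flagged for
#' proximity to the TSS (within \code{upstreamWindow} bp directly
#' upstream).
#'
#' @param calls translocation data.frame (breakend A = donor side).
#' @param annotations GRanges with a metadata column \code{class} taking
#'   values \code{"intron"}, \code{"ctcf_pair_window"},
#'   \code{"triple_gene_span"} and optionally \code{"gene"} (used to
#'   exclude intragenic positions from pattern 1), plus a \code{name}
#'   column; see [locusAnnotations()].
#' @param acceptorTss 0-based TSS position on the acceptor chromosome.
#' @param upstreamWindow width of the "directly upstream of the TSS"
#'   window in bp, default 600.
#' @return data.frame with columns \code{id}, \code{pattern} (factor
#'   "1","2","3","other"), \code{evidence} (matched annotation name) and
#'   \code{acceptorNearTss}.
#' @export
classifyPattern <- function(calls, annotations, acceptorTss,
                            upstreamWindow = 600) {
  stopifnot(is.data.frame(calls), is(annotations, "GRanges"))
  needed <- c("intron", "ctcf_pair_window", "triple_gene_span")
  have <- unique(annotations$class)
  missing <- setdiff(needed, have)
  if (length(missing))
    stop("missing annotation class: ", paste(missing, collapse = ", "))
  ids <- if (!is.null(calls$id)) calls$id else seq_len(nrow(calls))
  pat <- character(nrow(calls))
  evid <- character(nrow(calls))
  ann <- split(annotations, annotations$class)
  genes <- if ("gene" %in% have) ann[["gene"]] else GRanges()
  for (i in seq_len(nrow(calls))) {
    p1 <- GRanges(calls$chromA[i], IRanges(calls$posA[i] + 1, width = 1))
    inAnn <- function(gr) {
      ov <- findOverlaps(p1, gr, ignore.strand = TRUE)
      if (length(ov)) subjectHits(ov)[1] else NA_integer_
    }
    hIntron <- inAnn(ann[["intron"]])
    hWin <- inAnn(ann[["ctcf_pair_window"]])
    hTriple <- inAnn(ann[["triple_gene_span"]])
    hGene <- if (length(genes)) inAnn(genes) else NA_integer_
    if (!is.na(hIntron)) {
      pat[i] <- "3"; evid[i] <- annName(ann[["intron"]], hIntron)
    } else if (!is.na(hWin) && is.na(hGene)) {
      pat[i] <- "1"; evid[i] <- annName(ann[["ctcf_pair_window"]], hWin)
    } else if (!is.na(hTriple)) {
      pat[i] <- "2"; evid[i] <- annName(ann[["triple_gene_span"]], hTriple)
    } else {
      pat[i] <- "other"; evid[i] <- NA_character_
    }
  }
  nearTss <- calls$posB >= acceptorTss - upstreamWindow &
    calls$posB < acceptorTss
  data.frame(id = ids,
             pattern = factor(pat, levels = c("1", "2", "3", "other")),
             evidence = evid,
             acceptorNearTss = nearTss,
             stringsAsFactors = FALSE)
}

annName <- function(gr, i) {
  if (!is.null(gr$name)) as.character(gr$name[i]) else
    sprintf("%s:%d-%d", as.character(seqnames(gr)[i]), start(gr)[i] - 1,
            end(gr)[i])
}

#' Build the pattern annotation set from a locus model
#'
#' Convenience constructor of the [classifyPattern()] annotation GRanges
#' from a [LocusModel-class]: donor introns, the convergent-CTCF window,
#' the triple-gene span and the donor gene bodies.
#'
#' @param locus a [LocusModel-class]
#' @return annotation GRanges with \code{class} and \code{name} columns
#' @export
locusAnnotations <- function(locus) {
  stopifnot(is(locus, "LocusModel"))
  introns <- locus@donorIntrons
  win <- ctcfPairWindow(locus)
  triple <- tripleGeneSpan(locus)
  genes <- locus@donorGenes
  mk <- function(gr, class, name) {
    gr <- granges(gr)
    gr$class <- rep(class, length(gr))
    gr$name <- name
    gr
  }
  suppressWarnings(c(
    mk(introns, "intron",
       sprintf("%s_intron%d", introns$gene_id, introns$intron_number)),
    mk(win, "ctcf_pair_window", "ctcf_pair_window"),
    mk(triple, "triple_gene_span", "triple_gene_span"),
    mk(genes, "gene", genes$gene_id)))
}

#' Reconstruct the derived chromosome and feature-to-TSS distances
#'
#' Joins the retained donor segment to the retained acceptor segment of a
#' translocation and reports, for every donor feature surviving on the
#' derived chromosome, its distance to the acceptor TSS: the
#' breakend-to-TSS distance on the acceptor side plus the feature's
#' distance to the donor breakend along the retained side, measured from
#' the feature edge nearest the junction. Features on lost segments are
#' excluded; features straddling the junction get donor-side distance 0.
#'
#' @param call one-row translocation data.frame (breakend A = donor).
#' @param donorFeatures GRanges of donor features (e.g. enhancers) with
#'   names or a \code{name} column.
#' @param tss 0-based acceptor TSS position.
#' @param acceptorFeatures optional GRanges of acceptor features retained
#'   alongside the TSS (reported with their native TSS distance).
#' @return list with \code{features} (data.frame name, side,
#'   \code{distanceToTss} in bp, ordered outward from the TSS),
#'   \code{junctionDistance} (bp from junction to TSS) and the retained
#'   sides.
#' @export
reconstructDerivedLocus <- function(call, donorFeatures, tss,
                                    acceptorFeatures = NULL) {
  stopifnot(is.data.frame(call), nrow(call) == 1L)
  posA <- call$posA; sA <- as.character(call$strandA)
  posB <- call$posB; sB <- as.character(call$strandB)
  stopifnot(sA %in% c("+", "-"), sB %in% c("+", "-"))
  # acceptor side: the retained segment must carry the TSS
  tssRetained <- (sB == "+" && tss < posB) || (sB == "-" && tss >= posB)
  if (!tssRetained) stop("TSS not on derived chromosome")
  junctionDistance <- abs(posB - tss)
  feat <- donorFeatures
  s0 <- start(feat) - 1
  e0 <- end(feat)
  if (sA == "+") {          # left of posA retained
    keep <- s0 < posA
    donorOffset <- pmax(0, posA - e0)[keep]
  } else {                  # right of posA retained
    keep <- e0 > posA
    donorOffset <- pmax(0, s0 - posA)[keep]
  }
  nm <- featureNames(feat)[keep]
  dist <- junctionDistance + donorOffset
  df <- data.frame(name = nm, side = rep("donor", sum(keep)),
                   distanceToTss = as.numeric(dist),
                   stringsAsFactors = FALSE)
  if (!is.null(acceptorFeatures) && length(acceptorFeatures)) {
    af <- acceptorFeatures
    as0 <- start(af) - 1; ae0 <- end(af)
    # retained with the TSS-bearing acceptor segment
    akeep <- if (sB == "+") as0 < posB else ae0 > posB
    mid <- (as0 + ae0) / 2
    adf <- data.frame(name = featureNames(af)[akeep],
                      side = rep("acceptor", sum(akeep)),
                      distanceToTss = abs(mid - tss)[akeep],
                      stringsAsFactors = FALSE)
    df <- rbind(df, adf)
  }
  df <- df[order(df$distanceToTss, df$name), , drop = FALSE]
  rownames(df) <- NULL
  list(features = df,
       junctionDistance = as.numeric(junctionDistance),
       donorRetainedSide = if (sA == "+") "left" else "right",
       acceptorRetainedSide = if (sB == "+") "left" else "right")
}

featureNames <- function(gr) {
  if (!is.null(names(gr)) && any(nzchar(names(gr)))) names(gr)
  else if (!is.null(gr$name)) as.character(gr$name)
  else sprintf("feature_%d", seq_along(gr))
}

#' Check whether the acceptor CTCF insulator is separated from the TSS
#'
#' TRUE when an acceptor CTCF site and the TSS fall on opposite sides of
#' the acceptor breakend, i.e. the rearrangement separates the upstream
#' insulator site from the promoter it used to shield.
#'
#' @param call one-row translocation data.frame (breakend B = acceptor).
#' @param ctcfSites numeric vector of 0-based acceptor CTCF site
#'   positions (possibly empty).
#' @param tss 0-based acceptor TSS position.
#' @return logical flag
#' @export
insulatorSeparationCheck <- function(call, ctcfSites, tss) {
  stopifnot(is.data.frame(call), nrow(call) == 1L)
  if (!length(ctcfSites)) return(FALSE)
  b <- call$posB
  any((ctcfSites < b & tss >= b) | (ctcfSites >= b & tss < b))
}
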