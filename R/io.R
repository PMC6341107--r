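# Plain-text interchange formats. All on-disk coordinates are 0-based
# half-open (BED convention); headers document the convention. In-memory
# interval objects are ordinary 1-based GRanges.

#' Write / read a ChIP tag table
#'
#' Three-column TSV: chrom, pos (0-based 5' tag coordinate), strand.
#'
#' @param tags data.frame with columns chrom, pos, strand
#' @param file path
#' @return \code{readTagTable} returns the tag data.frame.
#' @export
writeTagTable <- function(tags, file) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tags)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# ChIP tag table; pos = 0-based 5' coordinate", con)
  writeLines("chrom\tpos\tstrand", con)
  writeLines(sprintf("%s\t%d\t%s", tags$chrom, as.integer(tags$pos),
                     tags$strand), con)
  invisible(file)
}

#' @rdname writeTagTable
#' @export
readTagTable <- function(file) {
  read.table(file, header = TRUE, sep = "\t", comment.char = "#",
             colClasses = c("character", "integer", "character"))
}

#' Write / read intervals as BED
#'
#' BED with 0-based half-open intervals; an optional name column makes
#' BED4. \code{readBed} returns a GRanges (1-based, as usual).
#'
#' @param gr GRanges (a \code{name} metadata column is written if present)
#' @param file path
#' @return \code{readBed} returns a GRanges.
#' @export
writeBed <- function(gr, file) {
  stopifnot(is(gr, "GRanges"))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr))
  if (!is.null(gr$name)) df$name <- gr$name
  write.table(df, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeBed
#' @export
readBed <- function(file) {
  df <- read.table(file, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1, df[[3]]))
  if (ncol(df) >= 4) gr$name <- df[[4]]
  if (ncol(df) >= 6) strand(gr) <- df[[6]]
  gr
}

#' Write / read a translocation call table
#'
#' Eight columns plus id: chromA, posA, strandA, chromB, posB, strandB,
#' quality, support. Positions are 0-based breakend coordinates; for each
#' breakend, strand "+" means the segment left of pos is retained on the
#' derived chromosome and "-" the segment right of it (documented in the
#' file header).
#'
#' @param calls translocation data.frame
#' @param file path
#' @return \code{readSvTable} returns the calls data.frame.
#' @export
writeSvTable <- function(calls, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "# translocation calls; pos = 0-based breakend coordinate",
    "# strand: + = segment left of pos retained, - = segment right retained"
  ), con)
  cols <- c("chromA", "posA", "strandA", "chromB", "posB", "strandB",
            "quality", "support")
  if ("id" %in% names(calls)) cols <- c(cols, "id")
  writeLines(paste(cols, collapse = "\t"), con)
  write.table(calls[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeSvTable
#' @export
readSvTable <- function(file) {
  read.table(file, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write / read a FISH tally table
#'
#' TSV with columns case_id, group, n_cells, n_aberrant.
#'
#' @param fish data.frame
#' @param file path
#' @return \code{readFishTable} returns the data.frame.
#' @export
writeFishTable <- function(fish, file) {
  stopifnot(all(c("case_id", "group", "n_cells", "n_aberrant") %in%
                  names(fish)))
  write.table(fish, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeFishTable
#' @export
readFishTable <- function(file) {
  read.table(file, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write / read a count matrix with gene metadata columns
#'
#' TSV with columns gene_id, chrom, length, biotype, tss, then one column
#' per sample.
#'
#' @param counts genes x samples matrix
#' @param geneModels gene model data.frame (see [computeFpkmTpm()])
#' @param file path
#' @return \code{readCountsTable} returns \code{list(counts, geneModels)}.
#' @export
writeCountsTable <- function(counts, geneModels, file) {
  gm <- geneModels[match(rownames(counts), geneModels$gene_id), ]
  df <- cbind(gm[, c("gene_id", "chrom", "length", "biotype", "tss")],
              as.data.frame(counts))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCountsTable
#' @export
readCountsTable <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  meta <- c("gene_id", "chrom", "length", "biotype", "tss")
  counts <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(counts) <- df$gene_id
  list(counts = counts,
       geneModels = df[, meta])
}

#' Serialize a locus model to YAML
#'
#' Requires the yaml package (Suggests).
#'
#' @param locus a [LocusModel-class]
#' @param file path
#' @return \code{file}, invisibly
#' @export
writeLocusYaml <- function(locus, file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("writeLocusYaml requires the yaml package")
  stopifnot(is(locus, "LocusModel"))
  obj <- list(
    donor_chrom = locus@donorChrom,
    acceptor_chrom = locus@acceptorChrom,
    chrom_lengths = as.list(locus@chromLengths),
    donor_enhancers = lapply(seq_along(locus@donorEnhancers), function(i)
      list(start = start(locus@donorEnhancers)[i] - 1,
           end = end(locus@donorEnhancers)[i],
           fold = locus@donorEnhancers$fold[i])),
    donor_ctcf_sites = lapply(seq_along(locus@donorCtcfSites), function(i)
      list(pos = start(locus@donorCtcfSites)[i] - 1,
           orientation = if (as.character(
             strand(locus@donorCtcfSites))[i] == "+") "forward"
             else "reverse")),
    donor_genes = lapply(seq_along(locus@donorGenes), function(i)
      list(gene_id = locus@donorGenes$gene_id[i],
           start = start(locus@donorGenes)[i] - 1,
           end = end(locus@donorGenes)[i],
           in_triple_span = locus@donorGenes$in_triple_span[i])),
    acceptor_tss = locus@acceptorTss,
    acceptor_ctcf_site = locus@acceptorCtcfSite)
  writeLines(yaml::as.yaml(obj), file)
  invisible(file)
}
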