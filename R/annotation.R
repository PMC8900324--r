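#' Construct a gene annotation
#'
#' Builds the annotation container used throughout the package: a
#' [GenomicRanges::GRanges-class] with one row per gene isoform, a `gene_id`
#' metadata column, and an `exons` metadata column holding a
#' [GenomicRanges::GRangesList-class] of exon intervals. All coordinates are
#' 1-based inclusive (the usual Bioconductor convention); [readGeneAnnotation()]
#' performs the 0-based half-open BED conversion on import.
#'
#' The TSS of a gene is its 5' end in transcription orientation (`start` on
#' the plus strand, `end` on the minus strand) and the cleavage (polyA) site
#' is its 3' end; see [tssPositions()] and [cleavageSites()].
#'
#' @param seqnames Chromosome names.
#' @param start,end 1-based inclusive gene bounds.
#' @param strand `"+"` or `"-"` per gene.
#' @param geneId Gene (isoform) identifiers.
#' @param exonStarts,exonEnds Optional list of integer vectors (one per gene,
#'   1-based inclusive, sorted, non-overlapping, within the gene). When
#'   omitted, each gene is a single exon.
#' @param seqlengths Optional named chromosome lengths.
#' @return A `GRanges` with `gene_id` and `exons` metadata columns.
#' @examples
#' geneAnnotation("chr1", 101, 2600, "+", "geneA",
#'                exonStarts = list(c(101, 1001)),
#'                exonEnds = list(c(400, 2600)))
#' @export
geneAnnotation <- function(seqnames, start, end, strand, geneId,
                           exonStarts = NULL, exonEnds = NULL,
                           seqlengths = NULL) {
  if (any(end < start))
    stop("invalid gene interval: end < start")
  gr <- GRanges(seqnames, IRanges(start, end), strand = strand,
                gene_id = as.character(geneId))
  if (is.null(exonStarts)) {
    exons <- GRangesList(lapply(seq_along(gr), function(i)
      granges(gr[i])))
  } else {
    exons <- GRangesList(lapply(seq_along(gr), function(i) {
      es <- exonStarts[[i]]; ee <- exonEnds[[i]]
      if (length(es) != length(ee) || any(ee < es))
        stop("invalid exon intervals for gene ", geneId[i])
      if (is.unsorted(es, strictly = TRUE) && length(es) > 1L)
        stop("exons must be sorted for gene ", geneId[i])
      if (length(es) > 1L && any(es[-1] <= ee[-length(ee)]))
        stop("exons overlap for gene ", geneId[i])
      if (min(es) < start[i] || max(ee) > end[i])
        stop("exons outside gene bounds for gene ", geneId[i])
      GRanges(seqnames[i], IRanges(es, ee), strand = strand[i])
    }))
  }
  mcols(gr)$exons <- exons
  if (!is.null(seqlengths))
    seqlengths(gr) <- seqlengths[seqlevels(gr)]
  names(gr) <- mcols(gr)$gene_id
  gr
}

#' Read gene annotations from a BED file
#'
#' Reads BED12 (exon block structure) or BED6 (single-exon genes) into the
#' package's annotation `GRanges` (see [geneAnnotation()]). BED's 0-based
#' half-open coordinates become 1-based inclusive on import, so a BED line
#' `chr1 100 2600 geneA 0 +` yields a gene at 101..2600 whose TSS is 101.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` with `gene_id` and `exons` metadata columns, one row
#'   per isoform.
#' @seealso [keepLongestIsoform()], [tssPositions()]
#' @export
readGeneAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  .validateBedLines(path)
  gr <- rtracklayer::import(path, format = "BED")
  if (any(width(gr) < 1L))
    stop("validation error: gene with end <= start in ", path)
  ids <- if (!is.null(mcols(gr)$name) && !all(is.na(mcols(gr)$name)))
    as.character(mcols(gr)$name) else paste0("gene", seq_along(gr))
  if (!is.null(mcols(gr)$blocks)) {
    exons <- rtracklayer::blocks(gr)
    names(exons) <- NULL
  } else {
    exons <- GRangesList(lapply(seq_along(gr), function(i) granges(gr[i])))
  }
  out <- granges(gr)
  mcols(out)$gene_id <- ids
  mcols(out)$exons <- exons
  names(out) <- ids
  out
}

# light structural validation so parse errors can name the offending line
.validateBedLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || grepl("^(track|browser|#)", ln)) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) < 3L)
      stop("parse error at line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop("parse error at line ", i, ": non-numeric coordinates")
    if (e <= s)
      stop("validation error at line ", i, ": end <= start")
  }
  invisible(TRUE)
}

#' Transcription start sites and cleavage sites
#'
#' Strand-aware 5' and 3' anchor positions of annotated genes (1-based).
#' On the plus strand the TSS is the gene start and the cleavage site the
#' gene end; on the minus strand the reverse.
#'
#' @param genes Annotation `GRanges` (see [geneAnnotation()]).
#' @return Named integer vector of positions.
#' @export
tssPositions <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
  names(pos) <- mcols(genes)$gene_id
  pos
}

#' @rdname tssPositions
#' @export
cleavageSites <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
  names(pos) <- mcols(genes)$gene_id
  pos
}

#' Keep the longest isoform per gene symbol
#'
#' When several isoforms share a gene symbol, only the longest is retained
#' (ties broken by annotation order). Symbols default to the part of
#' `gene_id` before the last underscore or dot, or to the `symbol` metadata
#' column when present.
#'
#' @param genes Annotation `GRanges`.
#' @param symbols Optional character vector of gene symbols parallel to
#'   `genes`.
#' @return The filtered `GRanges`.
#' @export
keepLongestIsoform <- function(genes, symbols = NULL) {
  if (is.null(symbols)) {
    symbols <- if (!is.null(mcols(genes)$symbol))
      as.character(mcols(genes)$symbol)
    else sub("[._][0-9]+$", "", mcols(genes)$gene_id)
  }
  keep <- unlist(lapply(split(seq_along(genes), symbols), function(idx) {
    idx[which.max(width(genes)[idx])]
  }), use.names = FALSE)
  genes[sort(keep)]
}

# strand-aware first exon index (transcription order)
.firstExonIndex <- function(gene) {
  if (as.character(strand(gene)) == "-") length(mcols(gene)$exons[[1]]) else 1L
}
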