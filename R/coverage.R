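#' Construct a CoverageTrack
#'
#' @param cov An [IRanges::RleList-class] of per-base counts, or a `GRanges`
#'   with a `score` column (expanded with [GenomicRanges::coverage()]).
#' @param strand `"+"` or `"-"`.
#' @param totalReads Total mapped reads of the library.
#' @param seqlengths Optional named chromosome lengths used to size the
#'   per-base vectors.
#' @return A [CoverageTrack-class].
#' @export
coverageTrack <- function(cov, strand, totalReads, seqlengths = NULL) {
  if (is(cov, "GRanges")) {
    if (!is.null(seqlengths))
      seqlengths(cov) <- seqlengths[seqlevels(cov)]
    w <- if (!is.null(mcols(cov)$score)) abs(mcols(cov)$score)
         else rep(1, length(cov))
    cov <- coverage(cov, weight = w)
  }
  new("CoverageTrack", cov = cov, strand = strand,
      totalReads = as.numeric(totalReads))
}

#' Read a bedGraph file into a CoverageTrack
#'
#' Expands a 4-column bedGraph (0-based half-open intervals) to dense
#' per-base coverage; overlapping intervals are summed. Values on the minus
#' strand may follow the negative-value convention of genome-browser tracks;
#' magnitudes are stored either way.
#'
#' @param path Path to a bedGraph file.
#' @param strand Which strand this file represents, `"+"` or `"-"`.
#' @param totalReads Total mapped reads of the library (for CPM/RPKM/TPM
#'   scaling downstream).
#' @param seqlengths Optional named chromosome lengths; intervals beyond a
#'   declared length raise an error.
#' @return A [CoverageTrack-class].
#' @examples
#' tf <- tempfile(fileext = ".bedGraph")
#' writeLines("chr1\t0\t3\t2", tf)
#' track <- readBedGraph(tf, "+", totalReads = 100)
#' as.numeric(track@cov$chr1)  # 2 2 2
#' @export
readBedGraph <- function(path, strand, totalReads, seqlengths = NULL) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e)
                   stop("parse error reading ", path, ": ",
                        conditionMessage(e)))
  if (!is.null(seqlengths)) {
    bad <- end(gr) > seqlengths[as.character(seqnames(gr))]
    if (any(bad, na.rm = TRUE))
      stop("interval beyond declared chromosome length in ", path)
  }
  coverageTrack(gr, strand = strand, totalReads = totalReads,
                seqlengths = seqlengths)
}

#' Write a CoverageTrack as bedGraph
#'
#' Inverse of [readBedGraph()]: runs of equal per-base coverage become
#' bedGraph intervals (0-based half-open). Zero runs are omitted. Minus-strand
#' tracks are written with positive magnitudes.
#'
#' @param track A [CoverageTrack-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  gr <- as(track@cov, "GRanges")
  gr <- gr[mcols(gr)$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# numeric per-base window [from, to] (1-based, inclusive) on one chromosome,
# zero-filled outside the stored/declared extent; attr "clipped" records
# whether clipping occurred
.windowValues <- function(rlelist, chrom, from, to) {
  if (!chrom %in% names(rlelist))
    stop("unknown chromosome: ", chrom)
  r <- rlelist[[chrom]]
  n <- length(r)
  lo <- max(1L, from); hi <- min(n, to)
  out <- numeric(to - from + 1L)
  if (lo <= hi)
    out[(lo - from + 1L):(hi - from + 1L)] <- as.numeric(r[lo:hi])
  attr(out, "clipped") <- from < 1L || to > n
  out
}

#' Extract sense-strand coverage over a gene
#'
#' Returns per-base coverage over `[TSS - upstream, cleavage + downstream]`
#' from the track matching the gene's strand, oriented 5' to 3' (minus-strand
#' genes are reversed). Windows overhanging the chromosome are zero-filled
#' and flagged with the `clipped` attribute.
#'
#' @param plus,minus [CoverageTrack-class] objects for the two strands.
#' @param gene A single-row annotation `GRanges`.
#' @param upstream,downstream Flank sizes in bp (defaults 0).
#' @return Numeric vector of length `upstream + width(gene) + downstream`,
#'   with attribute `clipped`.
#' @export
extractGeneCoverage <- function(plus, minus, gene, upstream = 0,
                                downstream = 0) {
  stopifnot(length(gene) == 1L)
  neg <- as.character(strand(gene)) == "-"
  track <- if (neg) minus else plus
  chrom <- as.character(seqnames(gene))
  from <- if (neg) start(gene) - downstream else start(gene) - upstream
  to <- if (neg) end(gene) + upstream else end(gene) + downstream
  v <- .windowValues(track@cov, chrom, from, to)
  clipped <- attr(v, "clipped")
  if (neg) v <- rev(v)
  attr(v, "clipped") <- clipped
  v
}

#' Min-max normalize a coverage vector
#'
#' Maps coverage onto `[0, 1]` via `(x - min(x)) / (max(x) - min(x))`, the
#' per-gene normalization applied before the wavelet decomposition. Constant
#' input has no dynamic range and is a degenerate signal: the caller must
#' exclude such genes.
#'
#' @param values Numeric vector, length at least 2.
#' @return Numeric vector in `[0, 1]` with `min = 0`, `max = 1`.
#' @examples
#' minmaxNormalize(c(2, 4, 6))  # 0 0.5 1
#' @export
minmaxNormalize <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("degenerate signal: constant coverage cannot be minmax-normalized")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Transcripts per million
#'
#' Classic TPM: per-gene count rates (count / length) rescaled to sum to
#' one million across genes.
#'
#' @param counts Named numeric vector of per-gene read counts.
#' @param lengths Named numeric vector of gene lengths in bp (same names).
#' @return Named numeric vector of TPM values summing to `1e6`.
#' @examples
#' computeTPM(c(a = 10, b = 10), c(a = 1000, b = 2000))
#' @export
computeTPM <- function(counts, lengths) {
  if (!all(names(counts) %in% names(lengths)))
    stop("counts and lengths must share names")
  lengths <- lengths[names(counts)]
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rates <- counts / lengths
  tot <- sum(rates)
  if (tot == 0) stop("all counts are zero; TPM undefined")
  1e6 * rates / tot
}

# 5' single-base anchor of each read
.fivePrimeEnds <- function(reads) resize(reads, width = 1L, fix = "start")

#' Count reads per gene
#'
#' Counts reads whose 5' end falls within the gene body, on the gene's
#' strand (the counting region behind TPM and the stable-gene selection).
#'
#' @param reads `GRanges` of mapped reads (or a [RunOnLibrary-class]).
#' @param genes Annotation `GRanges`.
#' @return Named integer vector of counts.
#' @export
countGeneReads <- function(reads, genes) {
  if (is(reads, "RunOnLibrary")) reads <- libraryReads(reads)
  fp <- .fivePrimeEnds(reads)
  n <- countOverlaps(genes, fp)
  names(n) <- mcols(genes)$gene_id
  n
}

#' Per-gene expression stability across a cohort
#'
#' Computes per-sample TPM over annotated gene bodies, then the across-sample
#' mean and coefficient of variation (population standard deviation divided
#' by the mean) per gene — the statistics behind stable-gene selection for
#' the wavelet analysis.
#'
#' @param cohort A [RunOnCohort-class].
#' @param genes Annotation `GRanges`.
#' @return `data.frame` with columns `gene_id`, `mean_tpm`, `cv`; the
#'   per-sample TPM matrix is attached as attribute `tpm`.
#' @seealso [selectStableGenes()]
#' @export
geneExpressionStats <- function(cohort, genes) {
  if (length(libraries(cohort)) < 2L)
    stop("need at least 2 samples to compute a CV")
  lens <- width(genes)
  names(lens) <- mcols(genes)$gene_id
  tpm <- vapply(libraries(cohort), function(lib)
    computeTPM(countGeneReads(lib, genes), lens),
    numeric(length(genes)))
  colnames(tpm) <- vapply(libraries(cohort), sampleId, character(1))
  mu <- rowMeans(tpm)
  popsd <- sqrt(rowMeans((tpm - mu)^2))
  out <- data.frame(gene_id = mcols(genes)$gene_id, mean_tpm = mu,
                    cv = ifelse(mu > 0, popsd / mu, 0),
                    row.names = NULL)
  attr(out, "tpm") <- tpm
  out
}

#' Select stably, highly transcribed genes
#'
#' Keeps genes with a coefficient of variation strictly below `cvMax` and a
#' mean TPM strictly above `tpmMin`. The defaults are the primary thresholds
#' of the wavelet gene selection (a CV below 0.55 and mean TPM above 150);
#' `cvMax = 0.85, tpmMin = 100` reproduces the wider second-tier set.
#'
#' @param stats Output of [geneExpressionStats()].
#' @param cvMax CV threshold (strict `<`).
#' @param tpmMin Mean-TPM threshold (strict `>`).
#' @return Character vector of gene ids.
#' @export
selectStableGenes <- function(stats, cvMax = 0.55, tpmMin = 150) {
  stats$gene_id[stats$cv < cvMax & stats$mean_tpm > tpmMin]
}
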