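#' Pause and gene-body window definitions
#'
#' Constructor for [PauseWindows-class]. The default scheme places the pause
#' region at offsets `[-50, +250)` from the TSS (L1 = 300 bp) and the gene
#' body from `+250` to the annotated cleavage site. The alternate scheme
#' used for cross-checking is `pauseWindows(20, 80, polyAOffset = 1000)`.
#'
#' @param upstream,downstream Pause-region extent in bp.
#' @param bodyStart Offset of the body start from the TSS; defaults to
#'   `downstream` so the two regions tile the gene.
#' @param polyAOffset Bases trimmed off the 3' end of the body.
#' @return A [PauseWindows-class].
#' @export
pauseWindows <- function(upstream = 50, downstream = 250,
                         bodyStart = downstream, polyAOffset = 0) {
  new("PauseWindows", upstream = upstream, downstream = downstream,
      bodyStart = bodyStart, polyAOffset = polyAOffset)
}

#' Pausing index from region counts
#'
#' The length-normalized density ratio
#' `(pauseCount / L1) / (bodyCount / L2)`.
#'
#' @param pauseCount,bodyCount Read counts in the pause region and gene body.
#' @param L1,L2 Region lengths in bp.
#' @return Numeric pausing index; `NA` where `bodyCount` is 0 (undefined,
#'   gene excluded from summaries).
#' @examples
#' pauseIndexFromCounts(30, 60, 300, 3000)  # 5
#' @export
pauseIndexFromCounts <- function(pauseCount, bodyCount, L1, L2) {
  ifelse(bodyCount > 0, (pauseCount / L1) / (bodyCount / L2), NA_real_)
}

#' Promoter-proximal pausing index
#'
#' For every gene at least `minGeneLength` bp long, counts sense-strand reads
#' whose 5' end falls in the pause region and in the gene body (see
#' [pauseWindows()]) and forms the length-normalized density ratio. Assigning
#' a read by its 5' end prevents double counting across the pause/body
#' boundary.
#'
#' @param reads `GRanges` of mapped reads or a [RunOnLibrary-class].
#' @param genes Annotation `GRanges`; isoforms should be reduced to one per
#'   gene first (see [keepLongestIsoform()]).
#' @param windows A [PauseWindows-class].
#' @param minGeneLength Genes shorter than this are removed (default 2000 bp).
#' @return `data.frame` with columns `gene_id`, `pause_count`, `body_count`,
#'   `L1`, `L2`, `pause_index` (`NA` where the body has no reads).
#' @export
pauseIndex <- function(reads, genes, windows = pauseWindows(),
                       minGeneLength = 2000) {
  if (is(reads, "RunOnLibrary")) reads <- libraryReads(reads)
  genes <- genes[width(genes) >= minGeneLength]
  if (!length(genes)) stop("no genes pass the length filter")
  fp <- .fivePrimeEnds(reads)
  tss <- tssPositions(genes)
  cs <- cleavageSites(genes)
  neg <- as.character(strand(genes)) == "-"
  L1 <- windows@upstream + windows@downstream
  # pause: offsets [-upstream, +downstream) ; body: [bodyStart, geneEnd - polyAOffset]
  pStart <- ifelse(neg, tss - windows@downstream + 1L, tss - windows@upstream)
  pEnd   <- ifelse(neg, tss + windows@upstream,        tss + windows@downstream - 1L)
  bStart <- ifelse(neg, cs + windows@polyAOffset,      tss + windows@bodyStart)
  bEnd   <- ifelse(neg, tss - windows@bodyStart,       cs - windows@polyAOffset)
  L2 <- bEnd - bStart + 1
  ok <- L2 > 0
  pauseGR <- GRanges(seqnames(genes), IRanges(pStart, pEnd),
                     strand = strand(genes))
  bodyGR <- GRanges(seqnames(genes)[ok], IRanges(bStart[ok], bEnd[ok]),
                    strand = strand(genes)[ok])
  pc <- countOverlaps(pauseGR, fp)
  bc <- integer(length(genes)); bc[ok] <- countOverlaps(bodyGR, fp)
  data.frame(gene_id = mcols(genes)$gene_id, pause_count = pc,
             body_count = bc, L1 = L1, L2 = pmax(L2, 0),
             pause_index = pauseIndexFromCounts(pc, bc, L1, pmax(L2, 1)),
             row.names = NULL)
}

#' Exon/intron contamination ratio
#'
#' Mature-mRNA contamination metric: per gene, reads are assigned by their
#' 5' end (sense strand) to exons or introns, both normalized by RPKM, and
#' the log2 ratio formed. The first exon in transcription order is excluded
#' (to avoid the initiation peak); genes with whole-gene RPKM below
#' `rpkmMin` are excluded as low-signal; genes with no intronic or no exonic
#' signal after filtering are dropped with a message. The sample summary is
#' the median of per-gene log ratios.
#'
#' @param reads `GRanges` of mapped reads or a [RunOnLibrary-class].
#' @param genes Annotation `GRanges` with exon structure; only genes with at
#'   least 2 exons contribute.
#' @param totalReads Library depth for RPKM scaling; defaults to
#'   `length(reads)`.
#' @param rpkmMin Low-signal filter on whole-gene RPKM (default 1).
#' @return List with `perGene` (`data.frame`: `gene_id`, `exon_rpkm`,
#'   `intron_rpkm`, `log_ratio`) and `median` (the sample summary).
#' @export
exonIntronRatio <- function(reads, genes, totalReads = NULL, rpkmMin = 1) {
  if (is(reads, "RunOnLibrary")) {
    if (is.null(totalReads)) totalReads <- totalReads(reads)
    reads <- libraryReads(reads)
  }
  if (is.null(totalReads)) totalReads <- length(reads)
  multi <- lengths(mcols(genes)$exons) >= 2L
  genes <- genes[multi]
  if (!length(genes)) stop("no multi-exon genes in the annotation")
  fp <- .fivePrimeEnds(reads)
  rpkm <- function(count, len) count / (len / 1e3) / (totalReads / 1e6)

  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    ex <- mcols(g)$exons[[1]]
    ex <- ex[-.firstExonIndex(g)]                       # drop initiation exon
    introns <- GenomicRanges::setdiff(granges(g), mcols(g)$exons[[1]])
    if (!length(introns)) return(NULL)
    ec <- sum(countOverlaps(ex, fp))
    ic <- sum(countOverlaps(introns, fp))
    el <- sum(width(ex)); il <- sum(width(introns))
    whole <- rpkm(ec + ic, el + il)
    if (whole < rpkmMin) return(NULL)
    data.frame(gene_id = mcols(g)$gene_id, exon_rpkm = rpkm(ec, el),
               intron_rpkm = rpkm(ic, il),
               log_ratio = log2(rpkm(ec, el) / rpkm(ic, il)))
  })
  per <- do.call(rbind, rows)
  if (is.null(per) || !nrow(per))
    stop("no genes retained for the exon/intron ratio")
  bad <- !is.finite(per$log_ratio)
  if (any(bad)) {
    message(sum(bad), " gene(s) with empty exonic or intronic signal excluded")
    per <- per[!bad, , drop = FALSE]
  }
  if (!nrow(per)) stop("no genes retained for the exon/intron ratio")
  list(perGene = per, median = median(per$log_ratio))
}

#' Genic to intergenic read ratio
#'
#' Reads overlapping the strand-agnostic union of annotated gene bodies
#' (by at least 1 bp) are genic; the rest are intergenic. Returns
#' `genic / intergenic`; `Inf` when no read is intergenic.
#'
#' @param reads `GRanges` of mapped reads or a [RunOnLibrary-class].
#' @param genes Annotation `GRanges`.
#' @return Numeric ratio (possibly `Inf`).
#' @export
geneIntergenicRatio <- function(reads, genes) {
  if (is(reads, "RunOnLibrary")) reads <- libraryReads(reads)
  if (!length(reads)) stop("no reads")
  genic <- sum(countOverlaps(reads, reduce(genes, ignore.strand = TRUE),
                             ignore.strand = TRUE) > 0)
  inter <- length(reads) - genic
  if (inter == 0) Inf else genic / inter
}

#' Short-read TSS ratio
#'
#' Among reads of at most `maxLen` nt (longer reads are filtered out
#' entirely), the fraction whose 5' end lies within `tssWindow` bp of a
#' same-strand annotated TSS. Biotin-truncated initiation fragments
#' concentrate this ratio near the TSS; handling fragments dilute it.
#'
#' @param reads `GRanges` of mapped reads or a [RunOnLibrary-class].
#' @param genes Annotation `GRanges`.
#' @param maxLen Maximum read length retained (default 30 nt).
#' @param tssWindow Half-width of the TSS window in bp (default 20).
#' @return Numeric ratio in `[0, 1]`.
#' @export
shortReadTssRatio <- function(reads, genes, maxLen = 30, tssWindow = 20) {
  if (is(reads, "RunOnLibrary")) reads <- libraryReads(reads)
  short <- reads[width(reads) <= maxLen]
  if (!length(short)) stop("no reads of length <= ", maxLen)
  tss <- tssPositions(genes)
  tssWin <- GRanges(seqnames(genes),
                    IRanges(pmax(1L, tss - tssWindow), tss + tssWindow),
                    strand = strand(genes))
  fp <- .fivePrimeEnds(short)
  near <- countOverlaps(fp, tssWin) > 0       # strand-aware by default
  sum(near) / length(short)
}

#' Positional nucleotide composition of reads
#'
#' Per read position, the fraction of reads (of sufficient length) carrying
#' each base — the read-content fingerprint in which poly(A)-tailed and
#' C-tailed library preparations stand out.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet-class] of read
#'   sequences.
#' @param maxPositions Cap on the number of positions reported (default: the
#'   longest read).
#' @return Numeric matrix `positions x c(A, C, G, T, N)`; each row sums to 1.
#' @export
nucleotideComposition <- function(seqs, maxPositions = NULL) {
  seqs <- as.character(seqs)
  seqs <- seqs[nzchar(seqs)]
  if (!length(seqs)) stop("no read sequences provided")
  widths <- nchar(seqs)
  P <- min(max(widths), if (is.null(maxPositions)) max(widths) else maxPositions)
  bases <- c("A", "C", "G", "T", "N")
  out <- matrix(0, nrow = P, ncol = 5L, dimnames = list(NULL, bases))
  for (p in seq_len(P)) {
    sel <- widths >= p
    b <- substr(seqs[sel], p, p)
    b[!b %in% bases] <- "N"
    counts <- table(factor(b, levels = bases))
    out[p, ] <- as.numeric(counts) / sum(counts)
  }
  out
}

#' Library-preparation sequence signature scores
#'
#' Two read-content fractions that expose prep chemistry: reads ending in a
#' long poly(A) run (circularization preps polyadenylate before reverse
#' transcription) and reads with a C-rich terminus (template-switch reverse
#' transcription appends C nucleotides).
#'
#' @param seqs Character vector or `DNAStringSet` of read sequences.
#' @param polyAMin Minimum terminal A-run length (default 8 nt).
#' @param cEndMin Minimum number of C within the terminal window (default 3).
#' @param window Terminal window size in nt (default 5).
#' @return Named numeric vector `c(polyA_fraction, terminal_C_fraction)`
#'   (zeros for empty input).
#' @export
prepSignatureScores <- function(seqs, polyAMin = 8, cEndMin = 3, window = 5) {
  seqs <- as.character(seqs)
  seqs <- seqs[nzchar(seqs)]
  if (!length(seqs))
    return(c(polyA_fraction = 0, terminal_C_fraction = 0))
  polyA <- grepl(paste0("A{", polyAMin, ",}$"), seqs)
  n <- nchar(seqs)
  tailseq <- substr(seqs, pmax(1L, n - window + 1L), n)
  nC <- nchar(tailseq) - nchar(gsub("C", "", tailseq, fixed = TRUE))
  c(polyA_fraction = mean(polyA), terminal_C_fraction = mean(nC >= cEndMin))
}

#' Library complexity metrics
#'
#' The fraction of distinct read placements (chromosome, start, end, strand)
#' among all reads, and the number of distinct genomic bases covered by at
#' least one read.
#'
#' @param reads `GRanges` of mapped reads or a [RunOnLibrary-class].
#' @return List with `unique_read_fraction` and `unique_bases_covered`.
#' @export
libraryComplexity <- function(reads) {
  if (is(reads, "RunOnLibrary")) reads <- libraryReads(reads)
  if (!length(reads))
    return(list(unique_read_fraction = NA_real_, unique_bases_covered = 0))
  uniq <- length(unique(granges(reads)))
  list(unique_read_fraction = uniq / length(reads),
       unique_bases_covered = sum(width(reduce(reads, ignore.strand = FALSE))))
}

#' Full QC report for one library
#'
#' Convenience wrapper assembling the formula-defined QC statistics of a
#' library: per-gene pausing indices, the exon/intron contamination summary,
#' the genic/intergenic ratio, the short-read TSS ratio, positional
#' nucleotide composition and prep-signature scores (when sequences are
#' present), and library complexity.
#'
#' @param library A [RunOnLibrary-class].
#' @param genes Annotation `GRanges`.
#' @param windows A [PauseWindows-class].
#' @return Named list of the individual metric results.
#' @export
qcReport <- function(library, genes, windows = pauseWindows()) {
  seqs <- mcols(libraryReads(library))$seq
  list(
    sample_id = sampleId(library),
    pause_index = pauseIndex(library, genes, windows),
    exon_intron = exonIntronRatio(library, genes),
    gene_intergenic_ratio = geneIntergenicRatio(library, genes),
    short_read_tss_ratio = shortReadTssRatio(library, genes),
    nucleotide_composition = if (!is.null(seqs)) nucleotideComposition(seqs),
    prep_signature = if (!is.null(seqs)) prepSignatureScores(seqs),
    complexity = libraryComplexity(library))
}
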