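# Shared fixtures, built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# two-gene annotation on a small chromosome: geneA (+, 2 exons), geneB (-)
makeToyGenes <- function() {
  geneAnnotation(
    seqnames = c("chr1", "chr1"),
    start = c(101, 5001), end = c(2600, 8000),
    strand = c("+", "-"),
    geneId = c("geneA", "geneB"),
    exonStarts = list(c(101, 1001), c(5001, 7001)),
    exonEnds = list(c(400, 2600), c(6000, 8000)),
    seqlengths = c(chr1 = 20000))
}

# reads GRanges from parallel vectors
makeReads <- function(start, end, strand, chrom = "chr1", seq = NULL,
                      seqlen = 20000) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand,
                seqlengths = setNames(seqlen, chrom))
  if (!is.null(seq)) mcols(gr)$seq <- seq
  gr
}

# small synthetic cohort shared across tests (cheap: 8 genes, shallow depth)
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cc <- cohortConfig(nGenes = 8, depthPerSample = 2.5e4, seed = 42)
      cache <<- generateCohort(cc)
    }
    cache
  }
})

protocolLabelsOf <- function(cohort) {
  lab <- cohortLabels(cohort)
  setNames(as.character(lab$protocol), lab$sample_id)
}
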