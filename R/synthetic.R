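#' Synthetic cohort configuration
#'
#' Constructor for [CohortConfig-class] with the calibrated package defaults:
#' a 100-gene genome (2-4 kb genes, 2-5 exons), 9 GRO-mode and 9 PRO-mode
#' libraries of ~300k reads. Protocol signatures (defaults):
#' \itemize{
#' \item 5' peak offset: GRO +20 bp, PRO +80 bp (peak width 30 bp) — the
#'   TSS-proximal coverage shift;
#' \item multiplicative high-frequency texture: amplitude 0.4 for both, with
#'   period 6 bp (GRO) versus 3 bp (PRO), phase-locked to genomic
#'   coordinates — the systematic texture carried by wavelet detail
#'   coefficients;
#' \item exon contamination weight: GRO 0.15, PRO 0.08 — mature-mRNA
#'   carryover, higher in GRO;
#' \item short-fragment rate: GRO 0.02, PRO 0.10 — sub-30-nt TSS-proximal
#'   fragments;
#' \item intergenic weight: GRO 0.05, PRO 0.10 — GRO libraries carry
#'   relatively more genic signal.
#' }
#' Prep signatures: `CIRC` appends poly(A) tails to half its reads,
#' `TSRT` appends terminal C-runs to half; `LIG`/`RPR` are tail-free.
#'
#' @param nGenes,geneLengthRange,exonsPerGene,nSamplesPerProtocol,depthPerSample,noiseSd,seed
#'   See [CohortConfig-class].
#' @param protocolParams,prepParams Optional overrides; partial lists are
#'   merged over the defaults.
#' @param preps Prep labels recycled over each protocol's samples (default
#'   `"LIG"` for all).
#' @return A [CohortConfig-class].
#' @export
cohortConfig <- function(nGenes = 100L, geneLengthRange = c(2000L, 4000L),
                         exonsPerGene = c(2L, 5L),
                         nSamplesPerProtocol = 9L, depthPerSample = 3e5,
                         protocolParams = list(), prepParams = list(),
                         preps = "LIG", noiseSd = 0.1, seed = 1L) {
  defProt <- list(
    GRO = list(peakOffset = 20, peakWidth = 30, textureAmplitude = 0.4,
               texturePeriod = 6, exonContaminationWeight = 0.15,
               shortFragmentRate = 0.02, intergenicWeight = 0.05),
    PRO = list(peakOffset = 80, peakWidth = 30, textureAmplitude = 0.4,
               texturePeriod = 3, exonContaminationWeight = 0.08,
               shortFragmentRate = 0.10, intergenicWeight = 0.10))
  defPrep <- list(
    LIG  = list(polyATailRate = 0, terminalCRate = 0, fragmentLengthMean = 35),
    CIRC = list(polyATailRate = 0.5, terminalCRate = 0,
                fragmentLengthMean = 35),
    RPR  = list(polyATailRate = 0, terminalCRate = 0, fragmentLengthMean = 35),
    TSRT = list(polyATailRate = 0, terminalCRate = 0.5,
                fragmentLengthMean = 35))
  for (p in names(protocolParams))
    defProt[[p]][names(protocolParams[[p]])] <- protocolParams[[p]]
  for (p in names(prepParams))
    defPrep[[p]][names(prepParams[[p]])] <- prepParams[[p]]
  new("CohortConfig", nGenes = as.integer(nGenes),
      geneLengthRange = as.integer(geneLengthRange),
      exonsPerGene = as.integer(exonsPerGene),
      nSamplesPerProtocol = as.integer(nSamplesPerProtocol),
      depthPerSample = depthPerSample, protocolParams = defProt,
      prepParams = defPrep, preps = preps, noiseSd = noiseSd,
      seed = as.integer(seed))
}

# deterministic per-sample seed derivation (kept below 2^31)
.deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + 7919 * index) %% 2147483647)
}

# sample() treats a scalar first argument as 1:n; this keeps degenerate
# ranges (e.g. a fixed gene length) honest
.sampleFrom <- function(values, n) {
  values[sample.int(length(values), n, replace = TRUE)]
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes with exon/intron structure on one synthetic
#' chromosome, alternating gaps of 2-4 kb, with per-gene expression weights
#' (lognormal, fixed for the genome so cross-sample variation stays low).
#' Deterministic per seed.
#'
#' @param config A [CohortConfig-class].
#' @param seed Seed (defaults to the config master seed).
#' @return Annotation `GRanges` (see [geneAnnotation()]) with an extra
#'   `expr` metadata column; `seqlengths` are set.
#' @export
generateGenome <- function(config, seed = config@seed) {
  set.seed(seed)
  n <- config@nGenes
  lens <- .sampleFrom(seq(config@geneLengthRange[1],
                          config@geneLengthRange[2]), n)
  gaps <- sample(2000:4000, n, replace = TRUE)
  starts <- 3000L + cumsum(c(0L, head(lens + gaps, -1L))) + 1L
  ends <- starts + lens - 1L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("g%03d", seq_len(n))
  exonStarts <- vector("list", n); exonEnds <- vector("list", n)
  minSeg <- 60L
  for (i in seq_len(n)) {
    k <- .sampleFrom(seq(config@exonsPerGene[1], config@exonsPerGene[2]), 1L)
    while (lens[i] < minSeg * (2L * k - 1L) && k > 1L) k <- k - 1L
    nseg <- 2L * k - 1L
    widths <- minSeg + as.vector(rmultinom(1L, lens[i] - minSeg * nseg,
                                           rep(1, nseg)))
    bounds <- starts[i] + cumsum(c(0L, widths))
    exIdx <- seq(1L, nseg, by = 2L)
    exonStarts[[i]] <- bounds[exIdx]
    exonEnds[[i]] <- bounds[exIdx + 1L] - 1L
  }
  sl <- c(chrS1 = max(ends) + 3000L)
  genes <- geneAnnotation(rep("chrS1", n), starts, ends, strands, ids,
                          exonStarts, exonEnds, seqlengths = sl)
  expr <- rlnorm(n, 0, 0.25)
  mcols(genes)$expr <- expr / sum(expr)
  genes
}

# random read sequences drawn as substrings of a seeded background pool,
# with prep tails appended (tails emulate untrimmed library chemistry and
# are deliberately not part of the genomic interval)
.readSequences <- function(n, lens, prepPar) {
  poolLen <- 100000L
  pool <- paste(sample(c("A", "C", "G", "T"), poolLen, replace = TRUE),
                collapse = "")
  off <- sample.int(poolLen - max(lens), n, replace = TRUE)
  seqs <- substring(pool, off, off + lens - 1L)
  if (prepPar$polyATailRate > 0) {
    sel <- runif(n) < prepPar$polyATailRate
    seqs[sel] <- paste0(seqs[sel], strrep("A", 12L))
  }
  if (prepPar$terminalCRate > 0) {
    sel <- runif(n) < prepPar$terminalCRate
    seqs[sel] <- paste0(seqs[sel], strrep("C", 4L))
  }
  seqs
}

#' Generate one synthetic run-on library
#'
#' Draws reads from a per-gene mixture — a 5' peak at the protocol's offset
#' from the TSS, a uniform gene-body elongation component, an exon-biased
#' mature-mRNA contamination component, and intergenic background — with the
#' protocol's multiplicative high-frequency texture applied to the genic
#' sampling intensity before read sampling. Read sequences carry the prep's
#' tail signatures; coverage tracks are built from the reads themselves, so
#' coverage always equals the base-wise sum of read intervals.
#'
#' @param genes Annotation from [generateGenome()] (needs `expr` weights and
#'   `seqlengths`).
#' @param protocol `"GRO"` or `"PRO"`.
#' @param prep Library preparation label (must be present in the config's
#'   `prepParams`).
#' @param config A [CohortConfig-class].
#' @param seed Integer seed for this library.
#' @param sampleIdLabel Sample identifier.
#' @return A [RunOnLibrary-class] whose `truth` slot records the generating
#'   parameters.
#' @export
generateSample <- function(genes, protocol, prep, config, seed,
                           sampleIdLabel = paste0(protocol, "_", seed)) {
  pp <- config@protocolParams[[protocol]]
  kp <- config@prepParams[[prep]]
  if (is.null(pp) || is.null(kp)) stop("unknown protocol or prep")
  set.seed(seed)
  sl <- seqlengths(genes)[["chrS1"]]
  depth <- max(1L, round(config@depthPerSample *
                           rlnorm(1, 0, config@noiseSd)))
  nBg <- round(depth * pp$intergenicWeight)
  nGenic <- depth - nBg
  if (nGenic < 1L) stop("zero-depth configuration")
  geneCounts <- as.vector(rmultinom(1L, nGenic, mcols(genes)$expr))

  tss <- tssPositions(genes)
  neg <- as.character(strand(genes)) == "-"
  posList <- vector("list", length(genes) + 1L)
  lenList <- vector("list", length(genes) + 1L)
  strandList <- vector("list", length(genes) + 1L)
  for (i in seq_along(genes)) {
    cnt <- geneCounts[i]
    if (cnt == 0L) { posList[[i]] <- integer(); next }
    g <- genes[i]
    span <- start(g):end(g)
    w <- length(span)
    dir <- if (neg[i]) -1L else 1L
    peakCenter <- tss[i] + dir * pp$peakOffset
    peakDens <- dnorm(span, peakCenter, pp$peakWidth)
    s <- sum(peakDens)
    peakDens <- if (s > 0) peakDens / s else rep(1 / w, w)
    bodyDens <- rep(1 / w, w)
    exonBase <- rep(FALSE, w)
    for (e in seq_along(mcols(g)$exons[[1]])) {
      ex <- mcols(g)$exons[[1]][e]
      exonBase[(start(ex) - start(g) + 1L):(end(ex) - start(g) + 1L)] <- TRUE
    }
    exonDens <- exonBase / sum(exonBase)
    cw <- pp$exonContaminationWeight
    # component draw per read, then a textured position within the component
    comp <- sample(c("peak", "body", "contam"), cnt, replace = TRUE,
                   prob = c((1 - cw) * 0.3, (1 - cw) * 0.7, cw))
    tex <- 1 + pp$textureAmplitude * sin(2 * pi * span / pp$texturePeriod)
    tex[tex < 0] <- 0
    drawFrom <- function(dens, m) if (m > 0L)
      span[sample.int(w, m, replace = TRUE, prob = dens * tex)] else integer()
    posP <- drawFrom(peakDens, sum(comp == "peak"))
    posB <- drawFrom(bodyDens, sum(comp == "body"))
    posC <- drawFrom(exonDens, sum(comp == "contam"))
    pos <- c(posP, posB, posC)
    lens <- pmax(18L, round(rnorm(cnt, kp$fragmentLengthMean, 8)))
    # sub-30-nt TSS-proximal fragments replace a fraction of peak reads
    nPk <- length(posP)
    if (nPk > 0L && pp$shortFragmentRate > 0) {
      sh <- which(runif(nPk) < pp$shortFragmentRate)
      lens[sh] <- sample(15:30, length(sh), replace = TRUE)
    }
    posList[[i]] <- pos
    lenList[[i]] <- lens
    strandList[[i]] <- rep(if (neg[i]) "-" else "+", cnt)
  }
  # intergenic background: uniform over the complement of the gene union
  if (nBg > 0L) {
    inter <- GenomicRanges::gaps(reduce(genes, ignore.strand = TRUE))
    inter <- inter[as.character(strand(inter)) == "*"]
    iw <- width(inter)
    pick <- sample.int(length(inter), nBg, replace = TRUE,
                       prob = iw / sum(iw))
    posList[[length(genes) + 1L]] <-
      start(inter)[pick] + floor(runif(nBg) * iw[pick])
    lenList[[length(genes) + 1L]] <-
      pmax(18L, round(rnorm(nBg, 35, 8)))
    strandList[[length(genes) + 1L]] <-
      sample(c("+", "-"), nBg, replace = TRUE)
  }
  pos <- unlist(posList); lens <- unlist(lenList)
  strands <- unlist(strandList)
  negR <- strands == "-"
  readStart <- ifelse(negR, pmax(1L, pos - lens + 1L), pos)
  readEnd <- ifelse(negR, pos, pmin(sl, pos + lens - 1L))
  reads <- GRanges("chrS1", IRanges(readStart, readEnd), strand = strands,
                   seqlengths = c(chrS1 = sl))
  mcols(reads)$seq <- .readSequences(length(reads), width(reads), kp)
  total <- length(reads)
  plus <- coverageTrack(coverage(reads[strands == "+"]), "+", total)
  minus <- coverageTrack(coverage(reads[strands == "-"]), "-", total)
  new("RunOnLibrary", sampleId = sampleIdLabel, protocol = protocol,
      prep = prep, plus = plus, minus = minus, reads = reads,
      truth = list(protocol = protocol, prep = prep, seed = seed,
                   params = pp, prepParams = kp, depth = depth))
}

#' Generate a labeled synthetic cohort
#'
#' Generates the synthetic genome and `nSamplesPerProtocol` libraries per
#' protocol class with per-sample seeds derived from the master seed, so any
#' single library can be regenerated in isolation.
#'
#' @param config A [CohortConfig-class].
#' @return List with `cohort` (a [RunOnCohort-class]), `genes` (the
#'   annotation) and `config`.
#' @examples
#' \donttest{
#' cc <- cohortConfig(nGenes = 10, depthPerSample = 2e4, seed = 11)
#' gen <- generateCohort(cc)
#' cohortLabels(gen$cohort)
#' }
#' @export
generateCohort <- function(config) {
  if (config@nSamplesPerProtocol < 2L)
    stop("need at least 2 samples per protocol (LOOCV training folds must ",
         "contain both classes)")
  genes <- generateGenome(config)
  libs <- list(); rows <- list(); idx <- 0L
  for (protocol in c("GRO", "PRO")) {
    prepCycle <- rep(config@preps, length.out = config@nSamplesPerProtocol)
    for (j in seq_len(config@nSamplesPerProtocol)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%s_%02d", protocol, prepCycle[j], j)
      lib <- generateSample(genes, protocol, prepCycle[j], config,
                            seed = .deriveSeed(config@seed, idx),
                            sampleIdLabel = sid)
      libs[[idx]] <- lib
      rows[[idx]] <- data.frame(sample_id = sid, protocol = protocol,
                                prep = prepCycle[j], row.names = NULL)
    }
  }
  cohort <- new("RunOnCohort", libraries = libs,
                labels = do.call(rbind, c(rows, make.row.names = FALSE)))
  list(cohort = cohort, genes = genes, config = config)
}

#' Export a library to standard text formats
#'
#' Writes a library as the usual run-on deliverables: one bedGraph per
#' strand, a BED6 file of read intervals, and (when sequences are present) a
#' FASTA of read sequences.
#'
#' @param library A [RunOnLibrary-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
exportLibrary <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sampleId(library)
  paths <- c(
    plus = file.path(dir, paste0(id, ".pos.bedGraph")),
    minus = file.path(dir, paste0(id, ".neg.bedGraph")),
    reads = file.path(dir, paste0(id, ".reads.bed")))
  writeBedGraph(plusCoverage(library), paths[["plus"]])
  writeBedGraph(minusCoverage(library), paths[["minus"]])
  reads <- libraryReads(library)
  bed <- granges(reads)
  names(bed) <- NULL
  rtracklayer::export(bed, paths[["reads"]], format = "BED")
  seqs <- mcols(reads)$seq
  if (!is.null(seqs)) {
    fa <- file.path(dir, paste0(id, ".reads.fasta"))
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- paste0("read", seq_along(dss))
    Biostrings::writeXStringSet(dss, fa)
    paths <- c(paths, fasta = fa)
  }
  invisible(paths)
}
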