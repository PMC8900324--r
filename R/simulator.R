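#' Run-on simulator configuration
#'
#' Constructor for [SimConfig-class] with the package defaults: a 2000-nt
#' template of equal base proportions, 10000 initiation polymerases loaded
#' around the TSS (folded normal, sd 10 nt), 5000 elongating polymerases
#' uniform over the gene body, biotin-11-CTP chemistry (`labeledBase = "C"`),
#' a 100-nt run-on cap, exponential size selection with mean cutoff 25 nt, a
#' 25-nt mappability floor, and 4000 handling-fragment background reads.
#'
#' @param pBio Per-labeled-base halting probability (the biotin fraction of
#'   the labeled NTP pool). `0` emulates an unlabeled run-on (GRO-style, the
#'   cap alone terminates), `1` halts at the first labeled base.
#' @param templateLength,nInit,nElong,initMean,initSd,elongRange,labeledBase,maxRunon,sizeSelectMean,minMapLen,nBackground,backgroundLengthMean
#'   See [SimConfig-class].
#' @param seed Integer seed.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(pBio, templateLength = 2000L, nInit = 10000L,
                      nElong = 5000L, initMean = 0, initSd = 10,
                      elongRange = c(251L, 1750L), labeledBase = "C",
                      maxRunon = 100L, sizeSelectMean = 25,
                      minMapLen = 25L, nBackground = 4000L,
                      backgroundLengthMean = 30, seed = 1L) {
  new("SimConfig", templateLength = as.integer(templateLength),
      nInit = as.integer(nInit), nElong = as.integer(nElong),
      initMean = initMean, initSd = initSd,
      elongRange = as.integer(elongRange), labeledBase = labeledBase,
      pBio = pBio, maxRunon = as.integer(maxRunon),
      sizeSelectMean = sizeSelectMean, minMapLen = as.integer(minMapLen),
      nBackground = as.integer(nBackground),
      backgroundLengthMean = backgroundLengthMean, seed = as.integer(seed))
}

#' Generate a gene template with equal base proportions
#'
#' A random template sequence with exactly equal counts of A, C, G and T
#' (as equal as possible when `length` is not divisible by 4), shuffled by a
#' seeded RNG; identical seeds give identical templates.
#'
#' @param length Template length in nt (at least 4).
#' @param seed Integer seed.
#' @return Single character string of the template sequence.
#' @export
makeTemplate <- function(length = 2000L, seed = 1L) {
  if (length < 4L) stop("template length must be at least 4")
  set.seed(seed)
  base <- rep(c("A", "C", "G", "T"), length %/% 4L)
  extra <- c("A", "C", "G", "T")[seq_len(length %% 4L)]
  paste(sample(c(base, extra)), collapse = "")
}

# fold-and-clip: reflect negative draws onto the template, clip to its end
.foldPositions <- function(raw, templateLength) {
  pos <- abs(round(raw)) + 1L            # 1-based; TSS is position 1
  pmin(pos, templateLength)
}

#' Sample polymerase positions
#'
#' Initiation polymerases are drawn from `Normal(initMean, initSd)` around
#' the TSS, rounded, reflected onto the template (loading is centered at the
#' TSS; upstream draws fold downstream) and clipped to the template;
#' elongating polymerases are uniform over `elongRange`.
#'
#' @param config A [SimConfig-class].
#' @return List with integer vectors `init` and `elong` (1-based template
#'   positions).
#' @export
samplePolymerases <- function(config) {
  set.seed(config@seed)
  init <- .foldPositions(rnorm(config@nInit, config@initMean, config@initSd),
                         config@templateLength)
  elong <- if (config@nElong > 0L) {
    span <- seq(config@elongRange[1], config@elongRange[2])
    span[sample.int(length(span), config@nElong, replace = TRUE)]
  } else integer()
  list(init = init, elong = as.integer(elong))
}

#' Run-on extension with biotin-NTP termination
#'
#' Walks downstream from each polymerase position; at every occurrence of
#' the labeled base (the position itself included) extension halts with
#' probability `pBio` (a biotin-NTP was incorporated). Without a halt,
#' extension stops after `maxRunon` bases or at the template end, whichever
#' comes first.
#'
#' @param positions Integer vector of 1-based template positions.
#' @param template Template sequence (string, as from [makeTemplate()]).
#' @param pBio Per-labeled-base halting probability in `[0, 1]`.
#' @param maxRunon Maximum run-on distance in nt.
#' @param labeledBase The labeled nucleotide (default `"C"`).
#' @return Integer vector of termination positions (1-based, the last
#'   incorporated base), so the run-on stretch is
#'   `positions .. runOnExtend(...)` inclusive.
#' @examples
#' tmpl <- makeTemplate(40, seed = 3)
#' runOnExtend(1L, tmpl, pBio = 1, maxRunon = 100)  # first labeled base
#' @export
runOnExtend <- function(positions, template, pBio, maxRunon,
                        labeledBase = "C") {
  n <- nchar(template)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > n))
    stop("polymerase position outside the template")
  cap <- pmin(positions + as.integer(maxRunon) - 1L, n)
  if (pBio <= 0) return(cap)
  labpos <- which(strsplit(template, "")[[1]] == labeledBase)
  if (!length(labpos)) return(cap)
  # index of the first labeled base at/after each position, then a geometric
  # number of skipped labeled bases (failures before the halting success)
  first <- findInterval(positions - 1L, labpos) + 1L
  skip <- if (pBio >= 1) rep(0L, length(positions))
          else rgeom(length(positions), pBio)
  j <- first + skip
  term <- ifelse(j <= length(labpos), labpos[pmin(j, length(labpos))],
                 NA_integer_)
  out <- ifelse(is.na(term) | term > cap, cap, term)
  as.integer(out)
}

#' Exponential size selection
#'
#' Bead size selection modeled as a per-read cutoff drawn from an
#' exponential distribution with mean `meanCutoff`; a read is retained when
#' its length is at least its cutoff, so
#' `P(retained | length L) = 1 - exp(-L / meanCutoff)`, increasing in L.
#'
#' @param lengths Integer read lengths in nt.
#' @param meanCutoff Mean cutoff in nt (default 25).
#' @return List with logical `retained` and numeric `cutoffs`.
#' @export
sizeSelect <- function(lengths, meanCutoff = 25) {
  if (meanCutoff <= 0) stop("meanCutoff must be > 0")
  cutoffs <- rexp(length(lengths), rate = 1 / meanCutoff)
  list(retained = lengths >= cutoffs, cutoffs = cutoffs)
}

#' Simulate a pool of run-on reads near a TSS
#'
#' Full simulator pass: template generation, polymerase loading, run-on
#' extension with biotin termination, read formation, exponential size
#' selection and the mappability floor. Initiation-polymerase reads span
#' TSS to termination (the intact short nascent RNA); elongating-polymerase
#' reads span polymerase position to termination (the labeled 3' fragment of
#' a hydrolyzed long transcript); background handling fragments are
#' uniformly positioned with exponential lengths, independent of the run-on
#' chemistry.
#'
#' @param config A [SimConfig-class].
#' @return `data.frame` with columns `class` (`init`/`elong`/`background`),
#'   `start`, `end` (1-based inclusive), `length`, `cutoff`, `retained`,
#'   `mappable`. The template is attached as attribute `template`.
#' @export
simulateReads <- function(config) {
  template <- makeTemplate(config@templateLength, config@seed)
  pol <- samplePolymerases(config)      # reseeds with config@seed
  L <- config@templateLength
  initTerm <- runOnExtend(pol$init, template, config@pBio, config@maxRunon,
                          config@labeledBase)
  elongTerm <- runOnExtend(pol$elong, template, config@pBio, config@maxRunon,
                           config@labeledBase)
  bgStart <- sample.int(L, config@nBackground, replace = TRUE)
  bgLen <- pmax(1L, round(rexp(config@nBackground,
                               1 / config@backgroundLengthMean)))
  reads <- data.frame(
    class = rep(c("init", "elong", "background"),
                c(length(pol$init), length(pol$elong), config@nBackground)),
    start = c(rep(1L, length(pol$init)), pol$elong, bgStart),
    end = c(initTerm, elongTerm, pmin(bgStart + bgLen - 1L, L)))
  reads$length <- reads$end - reads$start + 1L
  ss <- sizeSelect(reads$length, config@sizeSelectMean)
  reads$cutoff <- ss$cutoffs
  reads$retained <- ss$retained
  reads$mappable <- reads$length >= config@minMapLen
  attr(reads, "template") <- template
  reads
}

#' Simulated TSS metagene and short-read summary
#'
#' Aggregates a [simulateReads()] pool into the simulator outputs: per-base
#' coverage of retained, mappable reads over the template; the density of
#' their 3' termination positions (the single-base polymerase-position
#' signal); the short-read TSS fraction (retained mappable reads of at most
#' `shortMax` nt whose 5' end lies within `tssWindow` nt of the TSS, over
#' all such short reads); and retention summaries. `meanRetainedLength`
#' describes the sequenced pool — all size-selection survivors — while the
#' coverage, 3'-end and short-read outputs additionally require
#' mappability. Identical seeds give identical traces.
#'
#' @param config A [SimConfig-class].
#' @param shortMax Short-read length ceiling in nt (default 30).
#' @param tssWindow TSS proximity window in nt (default 20).
#' @return List with `coverage`, `threePrimeDensity` (numeric vectors over
#'   the template), `shortReadTssFraction`, `meanRetainedLength`,
#'   `retentionRate`, `nRetained`, and the `reads` data.frame.
#' @export
simulateMetagene <- function(config, shortMax = 30L, tssWindow = 20L) {
  reads <- simulateReads(config)
  keep <- reads$retained & reads$mappable
  if (!any(keep)) stop("no reads retained after size selection")
  kept <- reads[keep, , drop = FALSE]
  L <- config@templateLength
  covStarts <- tabulate(kept$start, L)
  covEnds <- tabulate(pmin(kept$end + 1L, L + 1L), L + 1L)
  coverage <- cumsum(covStarts - covEnds[seq_len(L)])
  threePrime <- tabulate(kept$end, L)
  short <- kept[kept$length <= shortMax, , drop = FALSE]
  frac <- if (nrow(short)) mean(short$start - 1L <= tssWindow) else NA_real_
  list(coverage = coverage, threePrimeDensity = threePrime,
       shortReadTssFraction = frac,
       meanRetainedLength = mean(reads$length[reads$retained]),
       retentionRate = mean(reads$retained),
       nRetained = sum(reads$retained), reads = reads)
}

#' Short-read TSS fraction across a biotin-ratio grid
#'
#' Convenience sweep of [simulateMetagene()] over a grid of `pBio` values at
#' a shared seed, returning the short-read TSS fraction per grid point — the
#' summary in which the interior maximum (neither the lowest nor the highest
#' biotin ratio maximizes mappable TSS-proximal short reads) appears.
#'
#' @param pBioGrid Numeric vector of biotin ratios.
#' @param seed Integer seed shared across grid points.
#' @param ... Further arguments to [simConfig()].
#' @return Named numeric vector of short-read TSS fractions.
#' @export
shortReadSweep <- function(pBioGrid = c(0.01, 0.05, 0.1, 0.2, 0.35, 0.5,
                                        0.75, 1.0),
                           seed = 1L, ...) {
  vapply(pBioGrid, function(p)
    simulateMetagene(simConfig(pBio = p, seed = seed, ...))$shortReadTssFraction,
    numeric(1)) |> setNames(pBioGrid)
}
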