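#' @import methods
#' @importFrom S4Vectors Rle runValue
#' @importFrom IRanges IRanges RleList Views viewApply
#' @importFrom GenomicRanges GRanges GRangesList coverage reduce resize
#'   countOverlaps findOverlaps strand seqnames start end width mcols mcols<-
#'   psetdiff granges gaps
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels keepSeqlevels
#' @importFrom stats rnorm rexp rgeom runif rbinom rmultinom prcomp median sd
#'   dnorm quantile rlnorm predict setNames
#' @importFrom utils head tail
NULL

#' CoverageTrack: strand-specific per-base coverage
#'
#' Per-chromosome, per-base read coverage for one strand of a sequencing
#' library, stored run-length encoded, together with the total mapped read
#' count used for depth normalization (CPM/RPKM/TPM).
#'
#' @slot cov A [IRanges::RleList-class] of non-negative per-base counts,
#'   one element per chromosome.
#' @slot strand Either `"+"` or `"-"`. Minus-strand values are stored as
#'   magnitudes regardless of the sign convention of the source bedGraph.
#' @slot totalReads Total mapped reads in the library (both strands); must be
#'   positive whenever the track carries any signal.
#'
#' @seealso [readBedGraph()], [extractGeneCoverage()]
#' @export
setClass("CoverageTrack",
  representation(cov = "RleList", strand = "character", totalReads = "numeric"))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  mins <- vapply(object@cov, function(r) if (length(r)) min(runValue(r)) else 0,
                 numeric(1))
  if (length(mins) && any(mins < 0))
    msg <- c(msg, "coverage values must be non-negative")
  tot <- sum(vapply(object@cov, function(r) sum(as.numeric(runValue(r))),
                    numeric(1)))
  if (tot > 0 && object@totalReads <= 0)
    msg <- c(msg, "totalReads must be > 0 when the track carries signal")
  if (length(msg)) msg else TRUE
})

#' RunOnLibrary: one run-on sequencing library
#'
#' Container for a single library: enrichment protocol and library-prep
#' labels, strand-specific coverage, and (optionally) the individual mapped
#' reads with their sequences.
#'
#' @slot sampleId Character scalar identifier.
#' @slot protocol Enrichment protocol, `"GRO"` or `"PRO"`.
#' @slot prep Library preparation method (e.g. `"LIG"`, `"CIRC"`, `"RPR"`,
#'   `"TSRT"`), or `NA`.
#' @slot plus,minus [CoverageTrack-class] objects for the two strands.
#' @slot reads A [GenomicRanges::GRanges-class] of mapped reads (may be
#'   empty); the metadata column `seq` carries read sequences when available.
#' @slot truth List of generating parameters for synthetic libraries
#'   (empty for real data).
#'
#' @export
setClass("RunOnLibrary",
  representation(sampleId = "character", protocol = "character",
                 prep = "character", plus = "CoverageTrack",
                 minus = "CoverageTrack", reads = "GRanges", truth = "list"))

setValidity("RunOnLibrary", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be scalar")
  if (!object@protocol %in% c("GRO", "PRO", NA_character_))
    msg <- c(msg, "protocol must be 'GRO' or 'PRO'")
  if (object@plus@strand != "+" || object@minus@strand != "-")
    msg <- c(msg, "plus/minus slots must carry tracks of matching strand")
  if (length(msg)) msg else TRUE
})

#' RunOnCohort: a set of run-on libraries with protocol labels
#'
#' @slot libraries List of [RunOnLibrary-class] objects.
#' @slot labels `data.frame` with columns `sample_id`, `protocol`, `prep`.
#'
#' @export
setClass("RunOnCohort",
  representation(libraries = "list", labels = "data.frame"))

setValidity("RunOnCohort", function(object) {
  msg <- character()
  if (!all(vapply(object@libraries, is, logical(1), "RunOnLibrary")))
    msg <- c(msg, "libraries must all be RunOnLibrary objects")
  ids <- vapply(object@libraries, function(x) x@sampleId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated sample ids")
  if (!all(c("sample_id", "protocol") %in% colnames(object@labels)))
    msg <- c(msg, "labels must have sample_id and protocol columns")
  if (nrow(object@labels) != length(object@libraries) ||
      !setequal(object@labels$sample_id, ids))
    msg <- c(msg, "labels must match library sample ids")
  if (length(msg)) msg else TRUE
})

#' PauseWindows: promoter-proximal pause and gene-body regions
#'
#' Region definitions for the pausing index. The pause region spans
#' `[TSS - upstream, TSS + downstream)` in transcription orientation
#' (length `L1 = upstream + downstream`); the gene body runs from
#' `TSS + bodyStart` to the annotated cleavage site, optionally stopping
#' `polyAOffset` bases short of it.
#'
#' @slot upstream,downstream Pause-region extent in bp (defaults 50 and 250).
#' @slot bodyStart Offset of the body start from the TSS (default equals
#'   `downstream`, so pause and body tile the gene without gap or overlap).
#' @slot polyAOffset Bases trimmed off the 3' end of the body (default 0;
#'   the alternate scheme uses 1000).
#'
#' @seealso [pauseWindows()], [pauseIndex()]
#' @export
setClass("PauseWindows",
  representation(upstream = "numeric", downstream = "numeric",
                 bodyStart = "numeric", polyAOffset = "numeric"))

setValidity("PauseWindows", function(object) {
  msg <- character()
  if (object@upstream + object@downstream <= 0)
    msg <- c(msg, "pause region length L1 must be > 0")
  if (object@bodyStart < object@downstream)
    msg <- c(msg, "body region must not overlap the pause region")
  if (object@polyAOffset < 0) msg <- c(msg, "polyAOffset must be >= 0")
  if (length(msg)) msg else TRUE
})

#' WaveletFeatures: per-gene principal component scores of detail coefficients
#'
#' Result of the wavelet feature extraction: for every gene and every sample,
#' the first two principal component scores of the single-level detail
#' coefficients of minmax-normalized gene coverage.
#'
#' @slot scores `data.frame` with columns `gene_id`, `sample_id`, `pc1`, `pc2`.
#' @slot explainedVariance `data.frame` with columns `gene_id`, `ev1`, `ev2`
#'   (fractions of variance carried by the first two components).
#' @slot wavelet,mode Wavelet name and boundary mode used.
#' @slot skipped Character vector of gene ids excluded (constant coverage or
#'   too short for the filter).
#'
#' @export
setClass("WaveletFeatures",
  representation(scores = "data.frame", explainedVariance = "data.frame",
                 wavelet = "character", mode = "character",
                 skipped = "character"))

#' LOOCVResult: leave-one-out cross-validation of the protocol classifier
#'
#' @slot predictions `data.frame` with one row per (gene, held-out sample):
#'   columns `gene_id`, `sample_id`, `truth`, `predicted`, `decision`
#'   (signed decision value, positive toward the first protocol level).
#' @slot perGeneAccuracy `data.frame` with columns `gene_id`, `accuracy`,
#'   `n_folds`.
#' @slot levels Character vector of the two protocol levels; `decision > 0`
#'   favors `levels[1]`.
#' @slot nFolds Number of folds (= number of samples).
#' @slot skipped Gene ids skipped (constant feature scores).
#'
#' @export
setClass("LOOCVResult",
  representation(predictions = "data.frame", perGeneAccuracy = "data.frame",
                 levels = "character", nFolds = "integer",
                 skipped = "character"))

#' SimConfig: run-on read simulator configuration
#'
#' Parameters of the mechanistic simulator of reads near a transcription
#' start site: a random gene template with equal base proportions, initiation
#' polymerases loaded around the TSS, elongating polymerases in the gene
#' body, per-labeled-base Bernoulli termination during run-on, exponential
#' size selection, and a mappable-length floor.
#'
#' @slot templateLength Template length in nt (default 2000).
#' @slot nInit,nElong Numbers of initiation and elongating polymerases
#'   (defaults 10000 and 5000).
#' @slot initMean,initSd Normal distribution of initiation positions around
#'   the TSS, in nt (defaults 0 and 10); positions are rounded, reflected
#'   onto the template and clipped to `[0, templateLength)`.
#' @slot elongRange Two-element downstream interval (1-based, inclusive) from
#'   which elongating polymerase positions are drawn uniformly.
#' @slot labeledBase The biotin-labeled nucleotide (default `"C"`,
#'   biotin-11-CTP).
#' @slot pBio Probability of halting at each encountered labeled base
#'   (the biotin-NTP fraction of that base's pool), in `[0, 1]`.
#' @slot maxRunon Maximum run-on distance in nt when no labeled base halts
#'   extension (default 100).
#' @slot sizeSelectMean Mean of the exponential size-selection cutoff in nt
#'   (default 25).
#' @slot minMapLen Minimum mappable read length in nt (default 25); shorter
#'   reads are flagged unmappable.
#' @slot nBackground Number of handling-fragment background reads (default
#'   4000), uniformly positioned, with exponential lengths of mean
#'   `backgroundLengthMean` (default 30); independent of `pBio`.
#' @slot backgroundLengthMean Mean background fragment length in nt.
#' @slot seed Integer seed; all simulator randomness derives from it.
#'
#' @seealso [simConfig()], [simulateReads()], [simulateMetagene()]
#' @export
setClass("SimConfig",
  representation(templateLength = "integer", nInit = "integer",
                 nElong = "integer", initMean = "numeric", initSd = "numeric",
                 elongRange = "integer", labeledBase = "character",
                 pBio = "numeric", maxRunon = "integer",
                 sizeSelectMean = "numeric", minMapLen = "integer",
                 nBackground = "integer", backgroundLengthMean = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@pBio < 0 || object@pBio > 1) msg <- c(msg, "pBio must be in [0,1]")
  if (object@nInit <= 0L || object@nElong < 0L || object@nBackground < 0L)
    msg <- c(msg, "polymerase/background counts must be non-negative (nInit > 0)")
  if (length(object@elongRange) != 2L ||
      object@elongRange[1] < 1L ||
      object@elongRange[2] > object@templateLength ||
      object@elongRange[1] > object@elongRange[2])
    msg <- c(msg, "elongRange must lie within the template")
  if (!object@labeledBase %in% c("A", "C", "G", "T"))
    msg <- c(msg, "labeledBase must be one of A, C, G, T")
  if (object@sizeSelectMean <= 0) msg <- c(msg, "sizeSelectMean must be > 0")
  if (object@maxRunon < 1L) msg <- c(msg, "maxRunon must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CohortConfig: synthetic cohort generator configuration
#'
#' Parameters controlling a generated cohort of run-on libraries with
#' protocol- and prep-specific signatures. Protocol parameter lists carry,
#' per protocol (`GRO`, `PRO`): `peakOffset` (bp downstream of the TSS of the
#' 5' peak), `peakWidth` (bp), `textureAmplitude` and `texturePeriod` (the
#' multiplicative high-frequency coverage texture), `exonContaminationWeight`
#' (fraction of genic reads drawn from mature-mRNA exon contamination),
#' `shortFragmentRate` (fraction of peak reads emitted as sub-30-nt
#' fragments), and `intergenicWeight` (fraction of reads in unannotated
#' background). Prep parameter lists carry, per prep (`LIG`, `CIRC`, `RPR`,
#' `TSRT`): `polyATailRate`, `terminalCRate`, `fragmentLengthMean`.
#'
#' @slot nGenes Number of genes in the synthetic genome.
#' @slot geneLengthRange Two-element bp range of gene lengths.
#' @slot exonsPerGene Two-element range of exon counts per gene.
#' @slot nSamplesPerProtocol Samples per protocol class (default 9, for an
#'   18-sample cohort).
#' @slot depthPerSample Nominal reads per library.
#' @slot protocolParams Named list (`GRO`, `PRO`) of protocol signatures.
#' @slot prepParams Named list (`LIG`, `CIRC`, `RPR`, `TSRT`) of prep
#'   signatures.
#' @slot preps Character vector recycled over the samples of each protocol,
#'   assigning the library preparation method.
#' @slot noiseSd Lognormal sd of per-sample depth jitter.
#' @slot seed Master seed; per-sample seeds are derived from it.
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(nGenes = "integer", geneLengthRange = "integer",
                 exonsPerGene = "integer", nSamplesPerProtocol = "integer",
                 depthPerSample = "numeric", protocolParams = "list",
                 prepParams = "list", preps = "character",
                 noiseSd = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  need <- c("peakOffset", "peakWidth", "textureAmplitude", "texturePeriod",
            "exonContaminationWeight", "shortFragmentRate", "intergenicWeight")
  for (p in c("GRO", "PRO")) {
    pp <- object@protocolParams[[p]]
    if (is.null(pp) || !all(need %in% names(pp)))
      msg <- c(msg, paste0("protocolParams$", p, " must carry: ",
                           paste(need, collapse = ", ")))
    else {
      ratey <- unlist(pp[c("exonContaminationWeight", "shortFragmentRate",
                           "intergenicWeight")])
      if (any(ratey < 0 | ratey > 1))
        msg <- c(msg, "contamination/short-fragment/intergenic weights must be in [0,1]")
    }
  }
  for (p in names(object@prepParams)) {
    pp <- object@prepParams[[p]]
    rates <- unlist(pp[c("polyATailRate", "terminalCRate")])
    if (any(rates < 0 | rates > 1))
      msg <- c(msg, "prep tail rates must be in [0,1]")
  }
  if (object@depthPerSample <= 0) msg <- c(msg, "depthPerSample must be > 0")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MetageneProfile: TSS-anchored average coverage profile
#'
#' @slot sense,antisense Mean CPM per position, oriented 5' to 3' along the
#'   anchoring genes; length `upstream + downstream + 1`.
#' @slot positions Integer offsets from the TSS (`-upstream .. downstream`).
#' @slot nGenes Number of genes averaged.
#' @slot nSamples Number of libraries averaged.
#' @slot filters List describing the gene filters applied and their attrition.
#'
#' @seealso [buildMetagene()], [peakPosition()]
#' @export
setClass("MetageneProfile",
  representation(sense = "numeric", antisense = "numeric",
                 positions = "integer", nGenes = "integer",
                 nSamples = "integer", filters = "list"))

setValidity("MetageneProfile", function(object) {
  msg <- character()
  if (length(object@sense) != length(object@positions) ||
      length(object@antisense) != length(object@positions))
    msg <- c(msg, "profile and position lengths differ")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be > 0")
  if (length(msg)) msg else TRUE
})
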