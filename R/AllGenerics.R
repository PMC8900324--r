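#' Accessors for runonSig classes
#'
#' Small accessor generics: `sampleId`, `protocolLabel`, `prepLabel`,
#' `totalReads`, `plusCoverage`, `minusCoverage`, `libraryReads`,
#' `cohortLabels`, `libraries`, `featureScores`, `peakPosition`.
#'
#' @param x,object An object of the matching class.
#' @return The slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("protocolLabel", function(x) standardGeneric("protocolLabel"))
#' @rdname accessors
#' @export
setGeneric("prepLabel", function(x) standardGeneric("prepLabel"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("plusCoverage", function(x) standardGeneric("plusCoverage"))
#' @rdname accessors
#' @export
setGeneric("minusCoverage", function(x) standardGeneric("minusCoverage"))
#' @rdname accessors
#' @export
setGeneric("libraryReads", function(x) standardGeneric("libraryReads"))
#' @rdname accessors
#' @export
setGeneric("libraries", function(x) standardGeneric("libraries"))
#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))
#' @rdname accessors
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))
#' @rdname accessors
#' @export
setGeneric("perGeneAccuracy", function(x) standardGeneric("perGeneAccuracy"))
#' @rdname accessors
#' @export
setGeneric("foldPredictions", function(x) standardGeneric("foldPredictions"))

#' Peak position of a metagene profile
#'
#' Offset from the TSS (bp) of the maximum of the sense profile. Ties are
#' broken toward the TSS (smallest absolute offset; upstream of two
#' equidistant candidates loses to the one listed first).
#'
#' @param x A [MetageneProfile-class].
#' @return Integer offset in bp from the TSS.
#' @examples
#' prof <- new("MetageneProfile", sense = c(0, 1, 5, 5, 2),
#'             antisense = numeric(5), positions = -1:3,
#'             nGenes = 1L, nSamples = 1L, filters = list())
#' peakPosition(prof)  # plateau at +1..+2: tie broken toward the TSS
#' @export
setGeneric("peakPosition", function(x) standardGeneric("peakPosition"))

# ---- methods ----

#' @rdname accessors
#' @export
setMethod("sampleId", "RunOnLibrary", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("protocolLabel", "RunOnLibrary", function(x) x@protocol)
#' @rdname accessors
#' @export
setMethod("prepLabel", "RunOnLibrary", function(x) x@prep)
#' @rdname accessors
#' @export
setMethod("totalReads", "RunOnLibrary", function(x) x@plus@totalReads)
#' @rdname accessors
#' @export
setMethod("totalReads", "CoverageTrack", function(x) x@totalReads)
#' @rdname accessors
#' @export
setMethod("plusCoverage", "RunOnLibrary", function(x) x@plus)
#' @rdname accessors
#' @export
setMethod("minusCoverage", "RunOnLibrary", function(x) x@minus)
#' @rdname accessors
#' @export
setMethod("libraryReads", "RunOnLibrary", function(x) x@reads)
#' @rdname accessors
#' @export
setMethod("libraries", "RunOnCohort", function(x) x@libraries)
#' @rdname accessors
#' @export
setMethod("cohortLabels", "RunOnCohort", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("featureScores", "WaveletFeatures", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("perGeneAccuracy", "LOOCVResult", function(x) x@perGeneAccuracy)
#' @rdname accessors
#' @export
setMethod("foldPredictions", "LOOCVResult", function(x) x@predictions)

#' @describeIn accessors Number of libraries in a cohort.
#' @export
setMethod("length", "RunOnCohort", function(x) length(x@libraries))

#' @describeIn accessors Extract one library by index or sample id.
#' @param i Index or sample id.
#' @export
setMethod("[[", "RunOnCohort", function(x, i) {
  if (is.character(i)) {
    ids <- vapply(x@libraries, sampleId, character(1))
    i <- match(i, ids)
    if (is.na(i)) stop("unknown sample id")
  }
  x@libraries[[i]]
})

setMethod("show", "CoverageTrack", function(object) {
  n <- sum(vapply(object@cov, length, integer(1)))
  cat("CoverageTrack on strand", object@strand, "|",
      length(object@cov), "chromosome(s),", n, "bases |",
      "totalReads:", object@totalReads, "\n")
})

setMethod("show", "RunOnLibrary", function(object) {
  cat("RunOnLibrary", object@sampleId,
      sprintf("[%s-%s]", object@protocol, object@prep), "\n",
      " reads:", length(object@reads),
      "| totalReads:", object@plus@totalReads, "\n")
})

setMethod("show", "RunOnCohort", function(object) {
  tab <- table(object@labels$protocol)
  cat("RunOnCohort with", length(object@libraries), "libraries (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
})

setMethod("show", "PauseWindows", function(object) {
  cat(sprintf(
    "PauseWindows: pause [-%d, +%d) (L1 = %d bp), body from +%d to cleavage%s\n",
    object@upstream, object@downstream, object@upstream + object@downstream,
    object@bodyStart,
    if (object@polyAOffset > 0)
      sprintf(" - %d bp", object@polyAOffset) else ""))
})

setMethod("show", "WaveletFeatures", function(object) {
  cat("WaveletFeatures:", length(unique(object@scores$gene_id)), "genes x",
      length(unique(object@scores$sample_id)), "samples |",
      object@wavelet, "/", object@mode, "\n")
  if (length(object@skipped))
    cat("  skipped genes:", length(object@skipped), "\n")
})

setMethod("show", "LOOCVResult", function(object) {
  cat("LOOCVResult:", nrow(object@perGeneAccuracy), "genes,",
      object@nFolds, "folds | mean per-gene accuracy:",
      round(mean(object@perGeneAccuracy$accuracy), 3), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d nt template, %d init + %d elong + %d background reads, pBio = %.3g\n",
    object@templateLength, object@nInit, object@nElong, object@nBackground,
    object@pBio))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d genes, %d + %d samples (GRO + PRO), depth %g, seed %d\n",
    object@nGenes, object@nSamplesPerProtocol, object@nSamplesPerProtocol,
    object@depthPerSample, object@seed))
})

setMethod("show", "MetageneProfile", function(object) {
  cat(sprintf(
    "MetageneProfile: positions %d..%d, %d genes, %d sample(s); sense peak at %+d bp\n",
    min(object@positions), max(object@positions), object@nGenes,
    object@nSamples, peakPosition(object)))
})
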