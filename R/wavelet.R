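# Symlet-5 filter bank (10 taps). Decomposition low/high-pass and
# reconstruction low/high-pass; standard published orthonormal coefficients.
.sym5 <- local({
  dec_lo <- c( 0.027333068345077982,  0.029519490925774643,
              -0.039134249302383094,  0.199397533977393600,
               0.723407690402420600,  0.633978963458211900,
               0.016602105764522320, -0.175328089908450470,
              -0.021101834024758855,  0.019538882735286728)
  dec_hi <- rev(dec_lo) * rep(c(-1, 1), length.out = 10)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi))
})

.waveletFilters <- function(wavelet = "sym5") {
  if (!identical(wavelet, "sym5"))
    stop("only the symlet-5 wavelet is implemented")
  .sym5
}

# full linear convolution, identical to convolving sequences by hand
.convFull <- function(x, f) {
  stats::convolve(x, rev(f), type = "open")
}

# boundary extension by (L - 1) samples on each side
.extendSignal <- function(x, L, mode) {
  n <- length(x)
  p <- L - 1L
  switch(mode,
    symmetric = c(x[p:1], x, x[n:(n - p + 1L)]),
    antireflect = c(2 * x[1] - x[(p + 1L):2], x,
                    2 * x[n] - x[(n - 1L):(n - p)]),
    stop("unknown boundary mode: ", mode))
}

#' Single-level discrete wavelet transform
#'
#' Decomposes a signal into approximation (`cA`, low-frequency polymerase
#' signal shape) and detail (`cD`, high-frequency texture) coefficients with
#' the symlet-5 filter bank — one pass, as used for the protocol-signature
#' features.
#'
#' Boundary handling: `"antireflect"` (default) extends the signal
#' anti-symmetrically about its endpoint values, which continues constant
#' and linear trends exactly, so ramps produce vanishing detail
#' coefficients; `"symmetric"` is half-sample mirror padding;
#' `"periodization"` treats the signal as circular (even lengths only) and
#' is the orthonormal variant under which
#' `sum(x^2) = sum(cA^2) + sum(cD^2)` holds exactly.
#'
#' @param x Numeric signal, at least as long as the filter (10 taps).
#' @param wavelet Wavelet name; `"sym5"`.
#' @param mode Boundary mode, one of `"antireflect"`, `"symmetric"`,
#'   `"periodization"`.
#' @return List with elements `cA`, `cD`, `n` (original length), `wavelet`,
#'   `mode`. Coefficient length is `floor((n + 9) / 2)` for the padded modes
#'   and `n / 2` for periodization.
#' @seealso [idwtSingleLevel()]
#' @examples
#' d <- dwtSingleLevel(sin(seq(0, 4 * pi, length.out = 64)))
#' max(abs(idwtSingleLevel(d) - sin(seq(0, 4 * pi, length.out = 64))))
#' @export
dwtSingleLevel <- function(x, wavelet = "sym5",
                           mode = c("antireflect", "symmetric",
                                    "periodization")) {
  mode <- match.arg(mode)
  filt <- .waveletFilters(wavelet)
  L <- length(filt$dec_lo)
  n <- length(x)
  if (n < L)
    stop("signal shorter than the wavelet filter (", L,
         " taps); exclude this gene")
  if (mode == "periodization") {
    if (n %% 2L != 0L)
      stop("periodization mode requires an even-length signal")
    m <- n %/% 2L
    idx <- outer(2L * (seq_len(m) - 1L) + 5L, seq_len(L) - 1L, "-") %% n + 1L
    cA <- as.numeric(matrix(x[idx], m, L) %*% filt$dec_lo)
    cD <- as.numeric(matrix(x[idx], m, L) %*% filt$dec_hi)
  } else {
    ext <- .extendSignal(x, L, mode)
    m <- (n + L - 1L) %/% 2L
    take <- seq(L + 1L, by = 2L, length.out = m)
    cA <- .convFull(ext, filt$dec_lo)[take]
    cD <- .convFull(ext, filt$dec_hi)[take]
  }
  list(cA = cA, cD = cD, n = n, wavelet = wavelet, mode = mode)
}

#' Inverse single-level discrete wavelet transform
#'
#' Reconstructs the original signal from a [dwtSingleLevel()] decomposition;
#' reconstruction is exact to floating point for all boundary modes.
#'
#' @param decomposition List returned by [dwtSingleLevel()] (or a list with
#'   `cA`, `cD`, `n`, `wavelet`, `mode`).
#' @return Numeric vector of length `decomposition$n`.
#' @export
idwtSingleLevel <- function(decomposition) {
  filt <- .waveletFilters(decomposition$wavelet)
  L <- length(filt$rec_lo)
  cA <- decomposition$cA; cD <- decomposition$cD
  n <- decomposition$n
  m <- length(cA)
  if (decomposition$mode == "periodization") {
    out <- numeric(n)
    for (k in seq_len(m)) {
      pos <- (2L * (k - 1L) + 5L - (seq_len(L) - 1L)) %% n + 1L
      out[pos] <- out[pos] + filt$dec_lo * cA[k] + filt$dec_hi * cD[k]
    }
    return(out)
  }
  up <- function(c) { u <- numeric(2L * m); u[seq(1L, by = 2L,
                                                  length.out = m)] <- c; u }
  y <- .convFull(up(cA), filt$rec_lo) + .convFull(up(cD), filt$rec_hi)
  y[seq(L - 1L, length.out = n)]
}

# sign convention: orient each component so its largest-magnitude loading
# entry is positive (reproducible across runs and platforms)
.fixSigns <- function(rotation, scores) {
  for (k in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, k]))
    if (rotation[i, k] < 0) {
      rotation[, k] <- -rotation[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(rotation = rotation, scores = scores)
}

#' Principal component scores of a per-gene detail-coefficient matrix
#'
#' Columns are mean-centered (no variance scaling) and the samples projected
#' onto the top two right singular vectors. Components are oriented so that
#' the largest-magnitude loading entry is positive, fixing the sign
#' ambiguity.
#'
#' @param detailMatrix Numeric matrix, samples in rows, detail coefficients
#'   in columns (at least 3 rows).
#' @return List with `scores` (samples x 2, columns `pc1`, `pc2`) and
#'   `explainedVariance` (length-2 fractions). A matrix whose rows are all
#'   identical yields zero scores.
#' @export
perGenePCA <- function(detailMatrix) {
  if (!is.matrix(detailMatrix) || nrow(detailMatrix) < 3L)
    stop("need a matrix with at least 3 samples (rows)")
  if (!nrow(detailMatrix) || !ncol(detailMatrix))
    stop("rank-0 input")
  centered <- scale(detailMatrix, center = TRUE, scale = FALSE)
  if (all(abs(centered) < .Machine$double.eps * 100)) {
    sc <- matrix(0, nrow(detailMatrix), 2L,
                 dimnames = list(rownames(detailMatrix), c("pc1", "pc2")))
    return(list(scores = sc, explainedVariance = c(0, 0)))
  }
  p <- prcomp(detailMatrix, center = TRUE, scale. = FALSE, rank. = 2L)
  k <- ncol(p$x)
  scores <- cbind(p$x, matrix(0, nrow(p$x), 2L - k))[, 1:2, drop = FALSE]
  rot <- cbind(p$rotation, matrix(0, nrow(p$rotation), 2L - k))
  fx <- .fixSigns(rot[, 1:2, drop = FALSE], scores)
  scores <- fx$scores
  colnames(scores) <- c("pc1", "pc2")
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, explainedVariance = c(ev, 0, 0)[1:2])
}

#' Wavelet protocol-signature features for a cohort
#'
#' The feature-extraction pipeline: for every gene, sense-strand coverage is
#' extracted per sample, minmax-normalized, decomposed with a single-level
#' symlet-5 transform, and the per-gene matrix of detail coefficients
#' (samples x coefficients) reduced to per-sample (PC1, PC2) scores.
#' Genes with constant coverage in any sample, or shorter than the wavelet
#' filter, are skipped and reported.
#'
#' @param cohort A [RunOnCohort-class].
#' @param genes Annotation `GRanges` (typically the stable-gene set from
#'   [selectStableGenes()]).
#' @param wavelet,mode Passed to [dwtSingleLevel()].
#' @return A [WaveletFeatures-class].
#' @export
waveletFeatures <- function(cohort, genes, wavelet = "sym5",
                            mode = "antireflect") {
  libs <- libraries(cohort)
  ids <- vapply(libs, sampleId, character(1))
  scoreRows <- list(); evRows <- list(); skipped <- character()
  for (i in seq_along(genes)) {
    g <- genes[i]
    gid <- mcols(g)$gene_id
    mat <- NULL
    ok <- TRUE
    for (j in seq_along(libs)) {
      v <- extractGeneCoverage(plusCoverage(libs[[j]]),
                               minusCoverage(libs[[j]]), g)
      if (length(v) < 10L || diff(range(v)) == 0) { ok <- FALSE; break }
      cD <- dwtSingleLevel(minmaxNormalize(v), wavelet, mode)$cD
      if (is.null(mat))
        mat <- matrix(NA_real_, length(libs), length(cD))
      mat[j, ] <- cD
    }
    if (!ok) { skipped <- c(skipped, gid); next }
    pca <- perGenePCA(mat)
    scoreRows[[gid]] <- data.frame(gene_id = gid, sample_id = ids,
                                   pc1 = pca$scores[, 1],
                                   pc2 = pca$scores[, 2], row.names = NULL)
    evRows[[gid]] <- data.frame(gene_id = gid,
                                ev1 = pca$explainedVariance[1],
                                ev2 = pca$explainedVariance[2],
                                row.names = NULL)
  }
  if (!length(scoreRows)) stop("no genes usable for wavelet features")
  new("WaveletFeatures",
      scores = do.call(rbind, c(scoreRows, make.row.names = FALSE)),
      explainedVariance = do.call(rbind, c(evRows, make.row.names = FALSE)),
      wavelet = wavelet, mode = mode, skipped = skipped)
}

# strict 1D separation of two label groups
.separable1d <- function(v, isA) {
  max(v[isA]) < min(v[!isA]) || max(v[!isA]) < min(v[isA])
}

# exact strict linear separability of two 2D point sets. Candidate separator
# normals: cross-class point differences (vertex-vertex support) and
# perpendiculars of within-class differences (vertex-edge support) cover all
# maximum-margin configurations in the plane.
.separable2d <- function(X, isA) {
  A <- X[isA, , drop = FALSE]; B <- X[!isA, , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    cand[[length(cand) + 1L]] <- B[j, ] - A[i, ]
  within <- function(M) {
    if (nrow(M) < 2L) return(NULL)
    out <- list()
    for (i in seq_len(nrow(M) - 1L)) for (j in (i + 1L):nrow(M)) {
      d <- M[j, ] - M[i, ]
      out[[length(out) + 1L]] <- c(-d[2], d[1])
    }
    out
  }
  cand <- c(cand, within(A), within(B))
  for (w in cand) {
    if (all(w == 0)) next
    pa <- A %*% w; pb <- B %*% w
    if (max(pa) < min(pb) || max(pb) < min(pa)) return(TRUE)
  }
  FALSE
}

#' Categorize genes by protocol separability in PC space
#'
#' Classifies every gene by whether its per-sample (PC1, PC2) scores separate
#' the two protocols: `PC1_separable` when a threshold on PC1 alone splits
#' the labels perfectly, `plane_separable` when some line in the (PC1, PC2)
#' plane does, `not_separable` otherwise. Separability is exact (strict), not
#' fitted.
#'
#' @param features A [WaveletFeatures-class], or a `data.frame` with columns
#'   `gene_id`, `sample_id`, `pc1`, `pc2`.
#' @param labels Named character vector mapping sample ids to protocol
#'   labels (exactly two classes).
#' @return `data.frame` with columns `gene_id`, `category`.
#' @export
categorizeSeparation <- function(features, labels) {
  sc <- if (is(features, "WaveletFeatures")) featureScores(features)
        else features
  if (length(unique(labels)) != 2L)
    stop("need exactly two protocol labels")
  out <- lapply(split(sc, sc$gene_id), function(d) {
    isA <- labels[d$sample_id] == sort(unique(labels))[1]
    X <- cbind(d$pc1, d$pc2)
    cat <- if (.separable1d(d$pc1, isA)) "PC1_separable"
           else if (.separable2d(X, isA)) "plane_separable"
           else "not_separable"
    data.frame(gene_id = d$gene_id[1], category = cat, row.names = NULL)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[match(unique(sc$gene_id), res$gene_id), , drop = FALSE]
}
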