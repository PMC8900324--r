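#' Leave-one-out cross-validation of the linear protocol classifier
#'
#' For every gene, a linear-kernel support vector machine is trained on the
#' (PC1, PC2) scores of all samples but one and predicts the held-out
#' sample's protocol; every sample is held out once, so the number of folds
#' equals the number of samples. Per-gene accuracy is the fraction of
#' correctly predicted folds. Folds whose training set collapses to a single
#' class are skipped with a warning; genes with constant feature scores are
#' skipped and reported.
#'
#' The SVM is [e1071::svm()] with `kernel = "linear"` and soft-margin cost
#' `C`; the toolkit's internal feature standardization (`scale`) is kept at
#' its default.
#'
#' @param features A [WaveletFeatures-class] (or its `scores` data.frame).
#' @param labels Named character vector mapping sample ids to the two
#'   protocol labels.
#' @param C Soft-margin cost (default 1).
#' @param scale Passed to [e1071::svm()] (default `TRUE`, the toolkit
#'   default).
#' @return A [LOOCVResult-class].
#' @export
loocvPerGene <- function(features, labels, C = 1, scale = TRUE) {
  sc <- if (is(features, "WaveletFeatures")) featureScores(features)
        else features
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) stop("need exactly two protocol labels")
  samples <- unique(sc$sample_id)
  if (length(samples) < 3L) stop("need at least 3 samples for LOOCV")
  if (!all(samples %in% names(labels))) stop("labels missing for some samples")

  predRows <- list(); accRows <- list(); skipped <- character()
  for (gid in unique(sc$gene_id)) {
    d <- sc[sc$gene_id == gid, , drop = FALSE]
    d <- d[match(samples, d$sample_id), , drop = FALSE]
    X <- cbind(pc1 = d$pc1, pc2 = d$pc2)
    y <- factor(labels[samples], levels = lv)
    if (all(apply(X, 2, function(v) diff(range(v)) == 0))) {
      skipped <- c(skipped, gid)
      next
    }
    pred <- character(length(samples)); dec <- numeric(length(samples))
    keep <- rep(TRUE, length(samples))
    for (i in seq_along(samples)) {
      ytr <- y[-i]
      if (length(unique(ytr)) < 2L) {
        warning("fold with single-class training set skipped (gene ", gid,
                ", sample ", samples[i], ")")
        keep[i] <- FALSE
        next
      }
      fit <- suppressWarnings(
        e1071::svm(X[-i, , drop = FALSE], ytr, kernel = "linear",
                   cost = C, scale = scale, type = "C-classification"))
      p <- predict(fit, X[i, , drop = FALSE], decision.values = TRUE)
      dv <- as.numeric(attr(p, "decision.values"))
      # orient the decision value so positive always favors lv[1]
      dvName <- colnames(attr(p, "decision.values"))
      if (!startsWith(dvName, lv[1])) dv <- -dv
      pred[i] <- as.character(p)
      dec[i] <- dv
    }
    if (!any(keep)) next
    predRows[[gid]] <- data.frame(
      gene_id = gid, sample_id = samples[keep],
      truth = as.character(y)[keep], predicted = pred[keep],
      decision = dec[keep], row.names = NULL)
    accRows[[gid]] <- data.frame(
      gene_id = gid,
      accuracy = mean(pred[keep] == as.character(y)[keep]),
      n_folds = sum(keep), row.names = NULL)
  }
  if (!length(predRows)) stop("no genes evaluated")
  new("LOOCVResult",
      predictions = do.call(rbind, c(predRows, make.row.names = FALSE)),
      perGeneAccuracy = do.call(rbind, c(accRows, make.row.names = FALSE)),
      levels = lv, nFolds = length(samples), skipped = skipped)
}

#' Majority-rules protocol call per sample
#'
#' For every held-out sample, the modal predicted protocol across genes is
#' the sample's call. Exact vote ties are broken by the sign of the summed
#' SVM decision values and flagged.
#'
#' @param result A [LOOCVResult-class].
#' @return `data.frame` with columns `sample_id`, `truth`, `call`, `margin`
#'   (winning vote fraction), `tie`.
#' @export
majorityVote <- function(result) {
  preds <- foldPredictions(result)
  lv <- result@levels
  out <- lapply(split(preds, preds$sample_id), function(d) {
    votes <- table(factor(d$predicted, levels = lv))
    tie <- votes[1] == votes[2]
    call <- if (tie) {
      if (sum(d$decision) >= 0) lv[1] else lv[2]
    } else names(votes)[which.max(votes)]
    data.frame(sample_id = d$sample_id[1], truth = d$truth[1], call = call,
               margin = max(votes) / sum(votes), tie = tie,
               row.names = NULL)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[match(unique(preds$sample_id), res$sample_id), , drop = FALSE]
}

#' Classify a cohort's protocols from wavelet features
#'
#' End-to-end protocol classification: wavelet feature extraction over the
#' supplied gene set, per-gene leave-one-out SVM evaluation, and
#' majority-rules voting per sample. Deterministic given the inputs (the PCA
#' sign convention is fixed).
#'
#' @param cohort A [RunOnCohort-class] with protocol labels.
#' @param genes Annotation `GRanges` of the genes to use (must be non-empty).
#' @param C Soft-margin cost for the SVM.
#' @param wavelet,mode Passed to [waveletFeatures()].
#' @return List with `features` ([WaveletFeatures-class]), `loocv`
#'   ([LOOCVResult-class]), `calls` (per-sample majority votes),
#'   `meanGeneAccuracy`, and `sampleCallAccuracy`.
#' @export
classifyCohort <- function(cohort, genes, C = 1, wavelet = "sym5",
                           mode = "antireflect") {
  if (!length(genes)) stop("empty gene set")
  labels <- cohortLabels(cohort)
  labs <- setNames(as.character(labels$protocol), labels$sample_id)
  feats <- waveletFeatures(cohort, genes, wavelet, mode)
  cv <- loocvPerGene(feats, labs, C = C)
  calls <- majorityVote(cv)
  list(features = feats, loocv = cv, calls = calls,
       meanGeneAccuracy = mean(perGeneAccuracy(cv)$accuracy),
       sampleCallAccuracy = mean(calls$call == calls$truth))
}
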