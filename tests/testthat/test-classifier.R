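# build a feature table for n1 + n2 samples of two protocols at two centers
featTable <- function(center1, center2, n1 = 5, n2 = 5, jitter = 0.05,
                      genes = 1, seed = 1) {
  set.seed(seed)
  ids <- paste0("s", seq_len(n1 + n2))
  do.call(rbind, lapply(seq_len(genes), function(g) data.frame(
    gene_id = paste0("g", g), sample_id = ids,
    pc1 = c(rnorm(n1, center1[1], jitter), rnorm(n2, center2[1], jitter)),
    pc2 = c(rnorm(n1, center1[2], jitter), rnorm(n2, center2[2], jitter)))))
}
labelsFor <- function(n1, n2) setNames(rep(c("GRO", "PRO"), c(n1, n2)),
                                       paste0("s", seq_len(n1 + n2)))

test_that("well-separated clusters survive leave-one-out perfectly", {
  ft <- featTable(c(-1, 0), c(1, 0), genes = 3)
  cv <- loocvPerGene(ft, labelsFor(5, 5))
  expect_equal(perGeneAccuracy(cv)$accuracy, rep(1, 3))
  expect_equal(cv@nFolds, 10L)
  expect_equal(unique(perGeneAccuracy(cv)$n_folds), 10)
  # no sample is ever in its own training fold: every sample predicted once
  expect_equal(sort(unique(foldPredictions(cv)$sample_id)),
               sort(paste0("s", 1:10)))
})

test_that("fold count equals sample count", {
  for (n in c(4, 9)) {
    ft <- featTable(c(-1, 0), c(1, 0), n1 = n, n2 = n, genes = 1)
    cv <- loocvPerGene(ft, labelsFor(n, n))
    expect_equal(cv@nFolds, 2L * n)
    expect_equal(perGeneAccuracy(cv)$n_folds, 2 * n)
  }
})

test_that("label-permutation null accuracy sits in the oracle band", {
  # Permutation-null oracle: LOOCV of a soft-margin SVM on balanced labels
  # is biased BELOW chance (the held-out sample's class is the training
  # minority), so the expected null accuracy is ~0.35-0.45, not 0.5.
  set.seed(21)
  accs <- replicate(30, {
    ids <- paste0("s", 1:10)
    ft <- data.frame(gene_id = "g", sample_id = ids,
                     pc1 = rnorm(10), pc2 = rnorm(10))
    labs <- setNames(sample(rep(c("GRO", "PRO"), 5)), ids)
    mean(perGeneAccuracy(loocvPerGene(ft, labs))$accuracy)
  })
  expect_gt(mean(accs), 0.2)
  expect_lt(mean(accs), 0.6)
})

test_that("accuracy is invariant to rotating the PC plane (unscaled SVM)", {
  ft <- featTable(c(-1, 0.5), c(0.8, -0.4), jitter = 0.6, genes = 4,
                  seed = 5)
  labs <- labelsFor(5, 5)
  theta <- 35 * pi / 180
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  rot <- ft
  xy <- as.matrix(ft[, c("pc1", "pc2")]) %*% R
  rot$pc1 <- xy[, 1]; rot$pc2 <- xy[, 2]
  cv1 <- loocvPerGene(ft, labs, scale = FALSE)
  cv2 <- loocvPerGene(rot, labs, scale = FALSE)
  expect_equal(foldPredictions(cv1)$predicted, foldPredictions(cv2)$predicted)
  expect_equal(perGeneAccuracy(cv1)$accuracy, perGeneAccuracy(cv2)$accuracy)
})

test_that("constant-score genes are skipped, degenerate folds warned", {
  ft <- rbind(featTable(c(-1, 0), c(1, 0), genes = 1),
              data.frame(gene_id = "flat", sample_id = paste0("s", 1:10),
                         pc1 = 0, pc2 = 0))
  cv <- loocvPerGene(ft, labelsFor(5, 5))
  expect_equal(cv@skipped, "flat")
  expect_equal(nrow(perGeneAccuracy(cv)), 1)
  # two samples: every training fold is single-class
  ft2 <- featTable(c(-1, 0), c(1, 0), n1 = 1, n2 = 1, genes = 1)
  expect_error(loocvPerGene(ft2, labelsFor(1, 1)), "at least 3 samples")
  ft3 <- featTable(c(-1, 0), c(1, 0), n1 = 1, n2 = 2, genes = 1)
  expect_warning(cv3 <- loocvPerGene(ft3, labelsFor(1, 2)), "single-class")
})

test_that("majority voting is modal with the documented tie rule", {
  mk <- function(preds, decisions) {
    new("LOOCVResult",
        predictions = data.frame(
          gene_id = paste0("g", seq_along(preds)),
          sample_id = "s1", truth = "GRO", predicted = preds,
          decision = decisions),
        perGeneAccuracy = data.frame(gene_id = "g1", accuracy = 1,
                                     n_folds = 1),
        levels = c("GRO", "PRO"), nFolds = 1L, skipped = character())
  }
  v <- majorityVote(mk(c("GRO", "GRO", "PRO"), c(0.5, 0.2, -0.4)))
  expect_equal(v$call, "GRO")
  expect_false(v$tie)
  expect_equal(v$margin, 2 / 3)
  # exact tie: summed decision values (+0.4 - 0.1 > 0) pick GRO, flagged
  v2 <- majorityVote(mk(c("GRO", "PRO"), c(0.4, -0.1)))
  expect_equal(v2$call, "GRO")
  expect_true(v2$tie)
  v3 <- majorityVote(mk(rep("GRO", 4), rep(1, 4)))
  expect_equal(v3$margin, 1)
})

test_that("cohort classification is deterministic and self-consistent", {
  gen <- smallCohort()
  res1 <- classifyCohort(gen$cohort, gen$genes)
  res2 <- classifyCohort(gen$cohort, gen$genes)
  expect_identical(res1$calls, res2$calls)
  expect_identical(featureScores(res1$features), featureScores(res2$features))
  expect_gt(res1$meanGeneAccuracy, 0.7)
  expect_equal(res1$sampleCallAccuracy, 1)
  # majority-vote accuracy at least the mean per-gene accuracy here
  expect_gte(res1$sampleCallAccuracy, res1$meanGeneAccuracy)
  expect_error(classifyCohort(gen$cohort, gen$genes[0]), "empty gene set")
})
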