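test_that("detail coefficients annihilate constants and linear ramps", {
  expect_lt(max(abs(dwtSingleLevel(rep(1, 64))$cD)), 1e-10)
  ramp <- seq(0, 5, length.out = 100)
  expect_lt(max(abs(dwtSingleLevel(ramp)$cD)), 1e-8)
  expect_error(dwtSingleLevel(rnorm(5)), "shorter than the wavelet filter")
})

test_that("impulse response matches a direct convolution + downsampling oracle", {
  filt <- runonSig:::.sym5
  # impulse more than filter-length from either boundary: padding is zero
  x <- numeric(64); x[21] <- 1
  d <- dwtSingleLevel(x, mode = "antireflect")
  # brute-force linear convolution, no FFT, no extension machinery
  bruteConv <- function(x, f) {
    out <- numeric(length(x) + length(f) - 1)
    for (k in seq_along(out)) {
      js <- max(1, k - length(x) + 1):min(length(f), k)
      out[k] <- sum(f[js] * x[k - js + 1])
    }
    out
  }
  z <- bruteConv(x, filt$dec_hi)
  # extension shifts the convolution by L - 1 = 9; downsampled grid 2k
  oracle <- z[2 * seq_along(d$cD)]
  expect_equal(d$cD, oracle, tolerance = 1e-12)
  zA <- bruteConv(x, filt$dec_lo)
  expect_equal(d$cA, zA[2 * seq_along(d$cA)], tolerance = 1e-12)
})

test_that("single-level transform reconstructs perfectly in all modes", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(12:300, 1)
    x <- rnorm(n)
    for (mode in c("antireflect", "symmetric")) {
      d <- dwtSingleLevel(x, mode = mode)
      expect_lt(max(abs(idwtSingleLevel(d) - x)) / max(abs(x)), 1e-10)
      expect_equal(length(d$cA), (n + 9) %/% 2)
    }
    nEven <- 2 * (n %/% 2)
    xe <- x[seq_len(nEven)]
    dp <- dwtSingleLevel(xe, mode = "periodization")
    expect_lt(max(abs(idwtSingleLevel(dp) - xe)) / max(abs(xe)), 1e-10)
  }
})

test_that("periodization mode conserves energy exactly", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(2 * sample(10:200, 1))
    d <- dwtSingleLevel(x, mode = "periodization")
    expect_equal(sum(d$cA^2) + sum(d$cD^2), sum(x^2), tolerance = 1e-10)
  }
  expect_error(dwtSingleLevel(rnorm(33), mode = "periodization"), "even")
})

test_that("per-gene PCA recovers two-cluster geometry and centers scores", {
  M <- rbind(matrix(rep(c(1, 2, 3, 4), 4), 4, byrow = TRUE),
             matrix(rep(c(4, 3, 2, 1), 4), 4, byrow = TRUE))
  p <- perGenePCA(M)
  expect_equal(sum(p$scores[, 1]), 0, tolerance = 1e-9)
  expect_equal(sum(p$scores[, 2]), 0, tolerance = 1e-9)
  expect_equal(unname(abs(p$scores[, 1])),
               rep(unname(abs(p$scores[1, 1])), 8))
  expect_true(all(sign(p$scores[1:4, 1]) == -sign(p$scores[5:8, 1])))
  expect_equal(unname(p$scores[, 2]), rep(0, 8), tolerance = 1e-9)

  ident <- matrix(rep(c(5, 6, 7), 3), 3, byrow = TRUE)
  expect_equal(unname(perGenePCA(ident)$scores), matrix(0, 3, 2),
               ignore_attr = TRUE)
})

test_that("PCA scores match an independent SVD oracle on a 3x3 matrix", {
  set.seed(13)
  M <- matrix(rnorm(9), 3, 3)
  p <- perGenePCA(M)
  Mc <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(Mc)
  V <- sv$v[, 1:2]
  for (k in 1:2) if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  expect_equal(unname(p$scores), unname(Mc %*% V), tolerance = 1e-10)
})

test_that("PCA scores are invariant to consistent coefficient permutations", {
  set.seed(14)
  M <- matrix(rnorm(18 * 40), 18, 40)
  perm <- sample(40)
  p1 <- perGenePCA(M)
  p2 <- perGenePCA(M[, perm])
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-8)
  expect_equal(p1$explainedVariance, p2$explainedVariance, tolerance = 1e-10)
})

test_that("separation categories follow exact separability", {
  sc <- function(pc1, pc2) data.frame(
    gene_id = "g", sample_id = paste0("s", seq_along(pc1)),
    pc1 = pc1, pc2 = pc2)
  labs <- function(n1, n2) setNames(rep(c("GRO", "PRO"), c(n1, n2)),
                                    paste0("s", seq_len(n1 + n2)))
  expect_equal(categorizeSeparation(sc(c(-2, -1, 1, 2), rep(0, 4)),
                                    labs(2, 2))$category, "PC1_separable")
  # separable only along pc2
  expect_equal(categorizeSeparation(sc(c(0, 1, 0.5, 0.6), c(-1, -2, 1, 2)),
                                    labs(2, 2))$category, "plane_separable")
  # XOR-like interleaving: no linear separator
  expect_equal(categorizeSeparation(sc(c(-1, 1, -1, 1), c(-1, 1, 1, -1)),
                                    labs(2, 2))$category, "not_separable")
  expect_error(categorizeSeparation(sc(c(1, 2), c(0, 0)),
                                    setNames(c("GRO", "GRO"),
                                             c("s1", "s2"))),
               "two protocol labels")
})

test_that("cohort wavelet features have one (pc1, pc2) pair per gene-sample", {
  gen <- smallCohort()
  wf <- waveletFeatures(gen$cohort, gen$genes)
  sc <- featureScores(wf)
  expect_equal(nrow(sc), length(gen$genes) * 18)
  expect_true(all(c("gene_id", "sample_id", "pc1", "pc2") %in% colnames(sc)))
  # per-gene centering invariant
  bySum <- tapply(sc$pc1, sc$gene_id, sum)
  expect_lt(max(abs(bySum)), 1e-6)
})
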