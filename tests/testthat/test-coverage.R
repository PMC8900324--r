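test_that("BED12 import maps coordinates and strand-aware anchors", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t2600\tgeneA\t0\t+\t100\t2600\t0\t2\t300,1600\t0,900",
    "chr1\t100\t2600\tgeneB\t0\t-\t100\t2600\t0\t1\t2500\t0"), bed)
  genes <- readGeneAnnotation(bed)
  expect_equal(length(genes), 2L)
  # BED 0-based start 100 becomes 1-based 101
  expect_equal(unname(start(genes)), c(101L, 101L))
  expect_equal(unname(tssPositions(genes)), c(101, 2600))
  expect_equal(unname(cleavageSites(genes)), c(2600, 101))
  ex <- mcols(genes)$exons[[1]]
  expect_equal(start(ex), c(101L, 1001L))
  expect_equal(end(ex), c(400L, 2600L))
})

test_that("malformed annotation lines are rejected with a line number", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t2600\tok\t0\t+", "chr1\t500\t500\tbad\t0\t+"), bed)
  expect_error(readGeneAnnotation(bed), "line 2")
  writeLines(c("chr1\tnot_a_number\t2600\tbad\t0\t+"), bed)
  expect_error(readGeneAnnotation(bed), "line 1")
})

test_that("bedGraph expansion sums overlaps and stores minus magnitudes", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t3\t2", bg)
  tr <- readBedGraph(bg, "+", totalReads = 10)
  expect_equal(as.numeric(tr@cov$chr1), c(2, 2, 2))

  writeLines(c("chr1\t0\t2\t1", "chr1\t1\t3\t1"), bg)
  tr <- readBedGraph(bg, "+", totalReads = 10)
  expect_equal(as.numeric(tr@cov$chr1), c(1, 2, 1))

  writeLines("chr1\t0\t3\t-2", bg)
  tr <- readBedGraph(bg, "-", totalReads = 10)
  expect_equal(as.numeric(tr@cov$chr1), c(2, 2, 2))
})

test_that("bedGraph round-trips to identical per-base coverage", {
  set.seed(4)
  cov <- RleList(chr1 = Rle(sample(0:5, 200, replace = TRUE)))
  tr <- coverageTrack(cov, "+", totalReads = 500)
  f <- tempfile(fileext = ".bedGraph")
  writeBedGraph(tr, f)
  tr2 <- readBedGraph(f, "+", totalReads = 500)
  n <- length(tr@cov$chr1)
  expect_equal(as.numeric(tr2@cov$chr1[1:n]), as.numeric(tr@cov$chr1))
})

test_that("gene coverage extraction is strand-oriented and clip-flagged", {
  cov <- RleList(chr1 = Rle(c(rep(0, 100), 1, 2, 3, rep(0, 50))))
  plus <- coverageTrack(cov, "+", 10)
  minus <- coverageTrack(RleList(chr1 = Rle(c(rep(0, 100), 9, 8, 7,
                                              rep(0, 50)))), "-", 10)
  gPlus <- geneAnnotation("chr1", 101, 103, "+", "gp")
  gMinus <- geneAnnotation("chr1", 101, 103, "-", "gm")
  expect_equal(as.numeric(extractGeneCoverage(plus, minus, gPlus)), c(1, 2, 3))
  expect_equal(as.numeric(extractGeneCoverage(plus, minus, gMinus)), c(7, 8, 9))

  # minus-strand extraction equals the reverse of the mirrored plus case
  vP <- extractGeneCoverage(plus, minus, gPlus, upstream = 2, downstream = 4)
  mirrored <- coverageTrack(cov, "-", 10)
  vM <- extractGeneCoverage(plus, mirrored,
                            geneAnnotation("chr1", 101, 103, "-", "gm2"),
                            upstream = 4, downstream = 2)
  expect_equal(as.numeric(vM), rev(as.numeric(vP)))

  over <- extractGeneCoverage(plus, minus,
                              geneAnnotation("chr1", 2, 4, "+", "g0"),
                              upstream = 5)
  expect_true(attr(over, "clipped"))
  expect_equal(as.numeric(over[1:4]), rep(0, 4))  # zero-filled overhang
  expect_error(extractGeneCoverage(plus, minus,
                                   geneAnnotation("chrX", 1, 10, "+", "gx")),
               "unknown chromosome")
})

test_that("minmax normalization maps to [0,1] and rejects constants", {
  expect_equal(minmaxNormalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmaxNormalize(c(0, 0, 10)), c(0, 0, 1))
  expect_error(minmaxNormalize(c(5, 5, 5)), "degenerate")
  # affine invariance: a * x + b (a > 0) normalizes identically
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    expect_equal(minmaxNormalize(a * x + b), minmaxNormalize(x),
                 tolerance = 1e-10)
  }
})

test_that("TPM follows the rate normalization and sums to one million", {
  expect_equal(unname(computeTPM(c(a = 10, b = 10), c(a = 1000, b = 1000))),
               c(5e5, 5e5))
  tpm <- computeTPM(c(a = 10, b = 10), c(a = 1000, b = 2000))
  expect_equal(unname(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-8)
  expect_equal(unname(computeTPM(c(a = 7), c(a = 1234))), 1e6)
  expect_error(computeTPM(c(a = 0, b = 0), c(a = 10, b = 10)), "zero")
  set.seed(2)
  for (i in 1:10) {
    counts <- setNames(rpois(20, 50), paste0("g", 1:20))
    lens <- setNames(sample(500:5000, 20), paste0("g", 1:20))
    expect_equal(sum(computeTPM(counts, lens)), 1e6)
  }
})

test_that("stable-gene selection applies strict thresholds", {
  stats <- data.frame(gene_id = c("a", "b", "c"),
                      mean_tpm = c(151, 200, 149),
                      cv = c(0.54, 0.55, 0.2))
  expect_equal(selectStableGenes(stats, 0.55, 150), "a")
  expect_equal(selectStableGenes(data.frame(gene_id = character(),
                                            mean_tpm = numeric(),
                                            cv = numeric())),
               character())
})

test_that("longest isoform wins within a gene symbol", {
  genes <- geneAnnotation(rep("chr1", 3), c(101, 101, 5001),
                          c(2000, 3000, 6000), c("+", "+", "-"),
                          c("tp53.1", "tp53.2", "gapdh.1"))
  kept <- keepLongestIsoform(genes)
  expect_setequal(mcols(kept)$gene_id, c("tp53.2", "gapdh.1"))
})
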