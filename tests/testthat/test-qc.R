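test_that("pausing index follows the density-ratio formula", {
  expect_equal(pauseIndexFromCounts(30, 60, 300, 3000), 5)
  # uniform density gives PI = 1
  expect_equal(pauseIndexFromCounts(10, 100, 300, 3000), 1)
  expect_true(is.na(pauseIndexFromCounts(10, 0, 300, 3000)))
  # default windows: pause [-50, +250), L1 = 300
  w <- pauseWindows()
  expect_equal(w@upstream + w@downstream, 300)
})

test_that("pause index counts sense-strand 5' ends in the right regions", {
  genes <- makeToyGenes()  # geneA + at 101..2600 (TSS 101)
  # pause region [51, 350], body [351, 2600] (L2 = 2250)
  reads <- makeReads(
    start = c(60, 200, 340, 500, 900, 1500, 2200, 2590, 100),
    end = c(90, 230, 370, 530, 930, 1530, 2230, 2600, 130),
    strand = c(rep("+", 8), "-"))  # last read: wrong strand, ignored
  pi <- pauseIndex(reads, genes["geneA"])
  expect_equal(pi$pause_count, 3)
  expect_equal(pi$body_count, 5)
  expect_equal(pi$pause_index, (3 / 300) / (5 / 2250))
  # invariant: uniform depth scaling leaves PI unchanged
  pi3 <- pauseIndex(rep(reads, 3), genes["geneA"])
  expect_equal(pi3$pause_index, pi$pause_index)
  # genes shorter than 2000 bp are removed
  short <- geneAnnotation("chr1", 101, 1999, "+", "tiny")
  expect_error(pauseIndex(reads, short), "length filter")
})

test_that("exon/intron log2 ratio matches hand-built RPKM cases", {
  genes <- makeToyGenes()
  # geneA: first exon 101-400 excluded; exon2 1001-2600 (1600 bp),
  # intron 401-1000 (600 bp)
  mkreads <- function(ec, ic) {
    ex <- makeReads(seq(1001, length.out = ec, by = 2),
                    seq(1001, length.out = ec, by = 2) + 29, rep("+", ec))
    inr <- makeReads(seq(401, length.out = ic, by = 3),
                     seq(401, length.out = ic, by = 3) + 29, rep("+", ic))
    c(ex, inr)
  }
  # equal RPKM: ec/1600 == ic/600
  r0 <- exonIntronRatio(mkreads(16, 6), genes["geneA"])
  expect_equal(r0$perGene$log_ratio, 0)
  expect_equal(r0$median, 0)
  # 4x RPKM ratio -> log2 ratio of 2
  r2 <- exonIntronRatio(mkreads(32, 3), genes["geneA"])
  expect_equal(r2$perGene$log_ratio, 2)
  # low-signal gene (whole-gene RPKM < 1) excluded
  expect_error(exonIntronRatio(mkreads(16, 6), genes["geneA"],
                               totalReads = 5e7), "retained")
})

test_that("gene/intergenic ratio counts 1-bp overlaps as genic", {
  genes <- makeToyGenes()
  genic <- makeReads(seq(150, length.out = 80, by = 10),
                     seq(150, length.out = 80, by = 10) + 19, rep("+", 80))
  inter <- makeReads(seq(10000, length.out = 20, by = 30),
                     seq(10000, length.out = 20, by = 30) + 19, rep("+", 20))
  expect_equal(geneIntergenicRatio(c(genic, inter), genes), 4)
  expect_equal(geneIntergenicRatio(inter, genes), 0)
  expect_identical(geneIntergenicRatio(genic, genes), Inf)
  # read overlapping geneA (start 101) by exactly 1 bp is genic
  edge <- makeReads(82, 101, "+")
  expect_identical(geneIntergenicRatio(edge, genes), Inf)
  # known genic fraction f recovers f / (1 - f) exactly
  f <- 30 / 100
  mix <- c(genic[1:30], inter[rep(1:20, length.out = 70)])
  expect_equal(geneIntergenicRatio(mix, genes), f / (1 - f))
})

test_that("short-read TSS ratio filters long reads and matches counts", {
  genes <- makeToyGenes()  # TSS+ at 101, TSS- at 8000
  near <- makeReads(c(95, 101, 110), c(119, 125, 134), rep("+", 3))
  far <- makeReads(seq(3000, length.out = 7, by = 50),
                   seq(3000, length.out = 7, by = 50) + 24, rep("+", 7))
  long <- makeReads(500, 530, "+")  # 31 bp: filtered out entirely
  expect_equal(shortReadTssRatio(c(near, far, long), genes), 0.3)
  expect_equal(shortReadTssRatio(near, genes), 1)
  expect_error(shortReadTssRatio(long, genes), "length <= 30")
  # minus-strand TSS proximity uses the read 5' end (= interval end)
  nearMinus <- makeReads(7985, 8010, "-")
  expect_equal(shortReadTssRatio(nearMinus, genes), 1)
})

test_that("positional nucleotide composition handles ragged lengths", {
  m <- nucleotideComposition(c("AAAA", "AAAC"))
  expect_equal(unname(m[4, "A"]), 0.5)
  expect_equal(unname(m[4, "C"]), 0.5)
  id <- nucleotideComposition("ACGT")
  expect_equal(diag(id[, c("A", "C", "G", "T")]), rep(1, 4),
               ignore_attr = TRUE)
  ragged <- nucleotideComposition(c("AA", "AAG"))
  expect_equal(unname(ragged[3, "G"]), 1)  # position 3 seen in one read only
  expect_equal(unname(rowSums(ragged)), rep(1, 3), tolerance = 1e-9)
  expect_error(nucleotideComposition(character()), "no read sequences")
})

test_that("prep signature scores flag poly(A) tails and C-rich termini", {
  s <- c("GGGGGGAAAAAAAA",   # exactly 8 terminal A: counted
         "AGCTGGCCCT",       # ends GCCCT: 3 C in final 5: counted
         "ACGTACGT")         # neither
  sc <- prepSignatureScores(s)
  expect_equal(unname(sc["polyA_fraction"]), 1 / 3)
  expect_equal(unname(sc["terminal_C_fraction"]), 1 / 3)
  expect_equal(unname(prepSignatureScores(character())), c(0, 0))
})

test_that("library complexity uses distinct placements and base unions", {
  dup <- makeReads(rep(100, 10), rep(149, 10), rep("+", 10))
  expect_equal(libraryComplexity(dup)$unique_read_fraction, 0.1)
  disjoint <- makeReads(c(100, 300), c(149, 349), c("+", "+"))
  expect_equal(libraryComplexity(disjoint)$unique_bases_covered, 100)
  same <- makeReads(c(100, 100), c(149, 149), c("+", "+"))
  expect_equal(libraryComplexity(same)$unique_bases_covered, 50)
})
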