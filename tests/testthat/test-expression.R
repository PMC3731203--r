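test_that("expression windows follow the pad and head-exclusion rules", {
  # 101 codons -> stop codon first nt at L = 300; default window [12, 286)
  orfs <- orfFromCodons(rep("GCT", 99))
  fp <- data.frame(orf_id = "g", fiveprime = c(5L, 12L, 285L, 286L),
                   length = 28L, count = 1L)
  tr <- tracksFromTable(fp, orfs)
  wc <- orfWindowCount(tr, "g")
  expect_equal(wc$window_start, 12L)
  expect_equal(wc$window_end, 286L)
  expect_equal(wc$window_length_nt, 274L)
  # the read at +5 (inside the first 8 codons) and at 286 are excluded
  expect_equal(wc$window_reads, 2)

  # uniform coverage of 1 read/nt fills the window exactly
  fp2 <- data.frame(orf_id = "g", fiveprime = seq.int(-20L, 320L),
                    length = 28L, count = 1L)
  wc2 <- orfWindowCount(tracksFromTable(fp2, orfs), "g")
  expect_equal(wc2$window_reads, wc2$window_length_nt)
})

test_that("RPKM is definitional and scale invariant", {
  # 3-gene toy: counts {100, 300, 600}, windows of known length
  orfs <- OrfSet(stats::setNames(
    vapply(c(100, 100, 200), function(nc)
      paste0("ATG", strrep("GCT", nc - 2L), "TGA"), character(1)),
    c("g1", "g2", "g3")))
  wlen <- function(nc) (3 * (nc - 1) - 14) - 12
  mkfp <- function(counts) do.call(rbind, Map(function(id, n)
    data.frame(orf_id = id, fiveprime = 12L, length = 28L, count = n),
    c("g1", "g2", "g3"), counts))
  tab <- rpkmTable(tracksFromTable(mkfp(c(100L, 300L, 600L)), orfs), orfs)
  lib <- 1000
  expected <- c(100, 300, 600) / (c(wlen(100), wlen(100), wlen(200)) /
                                    1000) / (lib / 1e6)
  expect_equal(tab$rpkm, expected)
  expect_equal(attr(tab, "library_orf_reads"), lib)

  tab2 <- rpkmTable(tracksFromTable(mkfp(c(200L, 600L, 1200L)), orfs),
                    orfs)
  expect_equal(tab2$rpkm, tab$rpkm)
})

test_that("fold-change tables mean replicates and obey swap symmetry", {
  orfs <- buildSyntheticReference(n_orfs = 8L,
                                  length_range_codons = c(60L, 90L),
                                  seed = 151L)
  truth <- simulationTruth(orfs, seed = 152L)
  mk <- function(seed) {
    fp <- simulateFootprints(orfs, truth, 3e4, seed = seed)
    rpkmTable(poolAndFrameshift(fp, fixedCalibration(), orfs), orfs)
  }
  a1 <- mk(1L); a2 <- mk(2L); b1 <- mk(3L); b2 <- mk(4L)
  self <- foldChangeTable(a1, a1)
  expect_true(all(self$log2_fc == 0))
  fab <- foldChangeTable(list(a1, a2), list(b1, b2))
  fba <- foldChangeTable(list(b1, b2), list(a1, a2))
  expect_equal(fab$log2_fc, -fba$log2_fc)

  # a doubled gene flux shows up as a log2 fold change of about 1
  flux <- stats::setNames(rep(1, 8), orfIds(orfs))
  flux[1] <- 2
  t2 <- simulationTruth(orfs, gene_flux = flux, seed = 153L)
  dbl <- rpkmTable(poolAndFrameshift(
    simulateFootprints(orfs, t2, 1e5), fixedCalibration(), orfs), orfs)
  base <- rpkmTable(poolAndFrameshift(
    simulateFootprints(orfs, truth, 1e5, seed = 154L),
    fixedCalibration(), orfs), orfs)
  fc <- foldChangeTable(dbl, base)
  up <- fc$log2_fc[fc$orf_id == orfIds(orfs)[1]]
  # RPKM is compositional: doubling one of 8 similar genes inflates the
  # library total ~9/8, so the expected log2 change is ~1 - log2(9/8)
  expect_gt(up, 0.7)
  expect_lt(up, 0.95)
})

test_that("hypergeometric overlap equals exact combinatorics", {
  # background 10, |A| = |B| = 5, full overlap: C(5,5)C(5,0)/C(10,5)
  bg <- letters[1:10]
  r <- hypergeometricOverlap(letters[1:5], letters[1:5], bg)
  expect_equal(r$overlap_count, 5L)
  expect_equal(r$hypergeometric_p, 1 / choose(10, 5))

  r0 <- hypergeometricOverlap(letters[1:5], letters[6:10], bg)
  expect_equal(r0$hypergeometric_p, 1)  # P(X >= 0) = 1

  # enumeration oracle for all overlaps on small backgrounds
  set.seed(161)
  for (N in c(8L, 10L, 12L)) {
    bgN <- paste0("g", seq_len(N))
    a <- sample(bgN, 4L)
    b <- sample(bgN, 5L)
    got <- hypergeometricOverlap(a, b, bgN)
    expect_equal(got$hypergeometric_p,
                 hyperEnumerationP(4L, 5L, N, got$overlap_count),
                 tolerance = 1e-12, info = paste("N =", N))
  }

  expect_error(hypergeometricOverlap(c(bg[1:3], "zz"), bg[1:2], bg), "zz")
})

test_that("target-set K-S enrichment detects induced shifts", {
  expect_error(targetSetKs(data.frame(orf_id = "a", log2_fc = 1), "a"),
               "complement")

  set.seed(171)
  hits <- 0L
  for (trial in 1:10) {
    ids <- paste0("g", 1:1000)
    fc <- data.frame(orf_id = ids, log2_fc = rnorm(1000, 0, 0.25))
    targets <- sample(ids, 100)
    fc$log2_fc[fc$orf_id %in% targets] <-
      fc$log2_fc[fc$orf_id %in% targets] + 0.3
    r <- targetSetKs(fc, targets)
    if (r$ks_p < 1e-3) hits <- hits + 1L
    expect_gt(r$median_log2_target, r$median_log2_rest)
  }
  expect_gte(hits, 9L)

  # null targets give unremarkable p-values
  set.seed(172)
  ps <- replicate(20, {
    fc <- data.frame(orf_id = paste0("g", 1:500),
                     log2_fc = rnorm(500))
    targetSetKs(fc, sample(fc$orf_id, 50))$ks_p
  })
  expect_gt(sum(ps > 0.05), 15)
})

test_that("footprint/transcript correlation recovers construction", {
  ids <- paste0("g", 1:2000)
  mk <- function(v) data.frame(orf_id = ids, log2_fc = v)
  x <- rnorm(2000)
  expect_equal(riboseqRnaseqCorrelation(mk(x), mk(x))$r, 1)
  expect_equal(riboseqRnaseqCorrelation(mk(x), mk(-x))$r, -1)

  # shared transcriptional component with independent noise:
  # r = var(z) / (var(z) + var(e)) = 0.5 for unit variances
  set.seed(181)
  z <- rnorm(2000)
  ribo <- mk(z + rnorm(2000))
  rna <- mk(z + rnorm(2000))
  r <- riboseqRnaseqCorrelation(ribo, rna)$r
  expect_gt(r, 0.45)
  expect_lt(r, 0.55)

  expect_error(riboseqRnaseqCorrelation(mk(x)[1:2, ], mk(x)[1:2, ]), "3")
})

test_that("gene set files skip comments and blanks", {
  f <- tempfile()
  writeLines(c("# targets", "g1", "", "g2 "), f)
  expect_equal(readGeneSet(f), c("g1", "g2"))
})
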