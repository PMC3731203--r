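test_that("single-codon occupancy matches hand arithmetic", {
  # 12-codon gene; A-site in-frame counts at codon indices 4..11 are
  # [2,0,4,1,1,0,2,2]: included {4,6,7,8,10,11}, mean 2.0
  orfs <- orfFromCodons(rep("GCT", 10))  # 12 codons with start/stop
  cnt <- c(2L, 0L, 4L, 1L, 1L, 0L, 2L, 2L)
  m <- 4:11
  fp <- data.frame(orf_id = "g", fiveprime = 3L * m - 15L, length = 28L,
                   count = cnt)[cnt > 0, ]
  tr <- tracksFromTable(fp, orfs)
  occ <- singleCodonOccupancy(tr, orfs, sites = "A")
  expect_setequal(occ$codon_index, c(4L, 6L, 7L, 8L, 10L, 11L))
  expect_equal(occ$gene_mean_density, rep(2, 6))
  expect_equal(occ$occupancy[occ$codon_index == 6L], 2.0)
  expect_equal(occ$occupancy[occ$codon_index == 7L], 0.5)
})

test_that("occupancy is invariant under per-gene count scaling", {
  orfs <- orfFromCodons(rep("GCT", 20))
  set.seed(7)
  m <- 4:19
  cnt <- rpois(length(m), 3)
  fp <- data.frame(orf_id = "g", fiveprime = 3L * m - 15L, length = 28L,
                   count = cnt)[cnt > 0, ]
  occ1 <- singleCodonOccupancy(tracksFromTable(fp, orfs), orfs, "A")
  fp2 <- fp
  fp2$count <- fp2$count * 5L
  occ2 <- singleCodonOccupancy(tracksFromTable(fp2, orfs), orfs, "A")
  expect_equal(occ1$occupancy, occ2$occupancy)
})

test_that("uniform coverage gives unit occupancy at every site", {
  orfs <- orfFromCodons(rep("GCT", 30))
  nc <- nCodons(orfs)[["g"]]
  fp <- data.frame(orf_id = "g",
                   fiveprime = 3L * seq.int(-5L, nc + 5L) - 15L,
                   length = 28L, count = 1L)
  tr <- tracksFromTable(fp, orfs)
  occ <- singleCodonOccupancy(tr, orfs,
                              sites = c("-2", "-1", "E", "P", "A",
                                        "+1", "+2"))
  expect_true(all(occ$occupancy == 1))
})

test_that("replicate pooling sums tracks and commutes with counting", {
  sim <- sharedPerturbationSim()
  pooled <- poolReplicates(sim$tracks_wt, sim$tracks_mut)
  id <- orfIds(sim$orfs)[1]
  expect_equal(shiftedTrack(pooled, id),
               shiftedTrack(sim$tracks_wt, id) +
                 shiftedTrack(sim$tracks_mut, id))
  occ_p <- singleCodonOccupancy(pooled, sim$orfs, "A")
  occ_a <- singleCodonOccupancy(sim$tracks_wt, sim$orfs, "A")
  occ_b <- singleCodonOccupancy(sim$tracks_mut, sim$orfs, "A")
  key <- function(d) paste(d$orf_id, d$codon_index)
  # numerators on the pooled track equal sums of per-replicate numerators
  j <- intersect(intersect(key(occ_p), key(occ_a)), key(occ_b))
  np <- occ_p$numerator_reads[match(j, key(occ_p))]
  na <- occ_a$numerator_reads[match(j, key(occ_a))]
  nb <- occ_b$numerator_reads[match(j, key(occ_b))]
  expect_equal(np, na + nb)

  sub <- sim$orfs[1:3]
  other <- poolAndFrameshift(sim$wt[sim$wt$orf_id %in% orfIds(sub), ],
                             sim$cal, sub)
  expect_error(poolReplicates(sim$tracks_wt, other), "reference")
})

test_that("K-S comparison matches exact enumeration", {
  occ <- function(x) data.frame(codon = "AAA", site = "A", occupancy = x)
  same <- ksCompare(occ(c(1, 2, 3)), occ(c(1, 2, 3)), "AAA", "A")
  expect_equal(same$D_statistic, 0)
  expect_equal(same$p_value, 1)

  r <- ksCompare(occ(c(1, 2, 3)), occ(c(1.5, 2.5, 3.5)), "AAA", "A")
  expect_equal(r$D_statistic, 1 / 3)
  expect_equal(r$p_value, ksEnumerationP(c(1, 2, 3), c(1.5, 2.5, 3.5)))

  # exhaustive agreement for all sample-size pairs with n1+n2 <= 8
  set.seed(31)
  for (n1 in 2:6) for (n2 in 2:(8 - n1)) {
    x <- round(runif(n1), 3)
    y <- round(runif(n2) + 0.3, 3)
    got <- ksCompare(occ(x), occ(y), "AAA", "A")
    expect_equal(got$p_value, ksEnumerationP(x, y),
                 tolerance = 1e-12, info = paste(n1, n2))
    expect_equal(got$D_statistic, ksStatistic(x, y), info = paste(n1, n2))
  }

  empty <- data.frame(codon = character(), site = character(),
                      occupancy = numeric())
  expect_error(ksCompare(occ(1), empty, "AAA", "A"), "AAA")
})

test_that("the K-S grid flags exactly the perturbed codons", {
  sim <- sharedPerturbationSim()
  ow <- singleCodonOccupancy(sim$tracks_wt, sim$orfs,
                             sites = c("-2", "-1", "E", "P", "A",
                                       "+1", "+2"))
  om <- singleCodonOccupancy(sim$tracks_mut, sim$orfs,
                             sites = c("-2", "-1", "E", "P", "A",
                                       "+1", "+2"))
  grid <- ksHeatmap(om, ow)
  expect_equal(dim(grid$p), c(61L, 7L))
  ord <- order(grid$p)[1:3]
  hits <- data.frame(codon = rownames(grid$p)[arrayInd(ord, dim(grid$p))[, 1]],
                     site = colnames(grid$p)[arrayInd(ord, dim(grid$p))[, 2]])
  expect_setequal(hits$codon, c("AAA", "CAA", "GAA"))
  expect_true(all(hits$site == "A"))
})

test_that("null K-S p-values are approximately uniform", {
  orfs <- buildSyntheticReference(n_orfs = 15L,
                                  length_range_codons = c(120L, 200L),
                                  seed = 121L)
  t1 <- simulationTruth(orfs, seed = 122L)
  t2 <- simulationTruth(orfs, seed = 123L)
  cal <- fixedCalibration()
  ta <- poolAndFrameshift(simulateFootprints(orfs, t1, 2e5), cal, orfs)
  tb <- poolAndFrameshift(simulateFootprints(orfs, t2, 2e5), cal, orfs)
  oa <- singleCodonOccupancy(ta, orfs, "A")
  ob <- singleCodonOccupancy(tb, orfs, "A")
  grid <- ksHeatmap(oa, ob, sites = "A")
  p <- grid$p[!is.na(grid$p)]
  unif <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(unif$p.value, 0.01)
})

test_that("fold changes bin by coverage and respect read filters", {
  mk <- function(occ, reads) data.frame(
    orf_id = "g", codon_index = seq_along(occ), codon = "AAA", site = "A",
    occupancy = occ, numerator_reads = reads, gene_mean_density = 1)
  idm <- mk(c(1, 1.1), 2^c(0.05, 0.15))
  idw <- mk(c(1, 1), 2^c(0.05, 0.15))
  fc <- foldChangeVsCoverage(idm, idw, bin_width_log2 = 0.2)
  expect_equal(nrow(fc$binned), 1L)
  expect_equal(fc$binned$mean_fold_change, 1.05)

  ident <- foldChangeVsCoverage(idw, idw)
  expect_true(all(ident$instances$fold_change == 1))
  expect_true(all(ident$binned$mean_fold_change == 1))

  sim <- sharedPerturbationSim()
  ow <- singleCodonOccupancy(sim$tracks_wt, sim$orfs, "A")
  om <- singleCodonOccupancy(sim$tracks_mut, sim$orfs, "A")
  fc2 <- foldChangeVsCoverage(om, ow,
                              codon_sets = list(AAA = "AAA"))
  b <- fc2$binned
  wide <- merge(b[b$set == "AAA", c("bin", "mean_fold_change", "n")],
                b[b$set == "Other", c("bin", "mean_fold_change")],
                by = "bin", suffixes = c("_aaa", "_other"))
  wide <- wide[wide$n >= 20, ]
  expect_gt(nrow(wide), 0)
  expect_true(all(wide$mean_fold_change_aaa > wide$mean_fold_change_other))
})

test_that("mean ribosome density implies a >50-codon spacing budget", {
  expect_equal(interRibosomeSpacing(164), 164 / 3)
  expect_gt(interRibosomeSpacing(164), 50)
})
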