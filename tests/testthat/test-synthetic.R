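test_that("reference generation is seeded and honours usage weights", {
  a <- buildSyntheticReference(n_orfs = 6L, seed = 12L,
                               length_range_codons = c(30L, 50L))
  b <- buildSyntheticReference(n_orfs = 6L, seed = 12L,
                               length_range_codons = c(30L, 50L))
  expect_identical(as.character(codingSeqs(a)), as.character(codingSeqs(b)))
  expect_identical(as.character(upstreamFlank(a)),
                   as.character(upstreamFlank(b)))

  w <- stats::setNames(rep(1, 61),
                       setdiff(names(Biostrings::GENETIC_CODE),
                               c("TAA", "TAG", "TGA")))
  w["AAA"] <- 0
  noAAA <- buildSyntheticReference(n_orfs = 10L, seed = 4L,
                                   length_range_codons = c(30L, 50L),
                                   codon_usage_weights = w)
  inst <- enumerateCodonInstances(noAAA, "AAA")
  # in-frame AAA can only arise in the start/stop codons, never the body
  expect_true(all(inst$codon_index %in%
                    c(0L, nCodons(noAAA)[inst$orf_id] - 1L)))
  scan <- sum(vapply(as.character(codingSeqs(noAAA)), function(s)
    length(scanInstances(s, "AAA")), integer(1)))
  expect_equal(nrow(inst), scan)

  expect_error(buildSyntheticReference(codon_usage_weights =
                                         stats::setNames(0, "AAA")),
               "positive")
})

test_that("null simulation gives uniform P-site usage within genes", {
  orfs <- buildSyntheticReference(n_orfs = 10L,
                                  length_range_codons = c(80L, 120L),
                                  seed = 21L)
  truth <- simulationTruth(orfs, init_peak_prob = 0, seed = 22L)
  reads <- simulateFootprints(orfs, truth, 1e5)
  pvals <- vapply(orfIds(orfs), function(id) {
    sub <- reads[reads$orf_id == id, ]
    counts <- tapply(sub$count, sub$psite_index, sum)
    eligible <- seq.int(3L, nCodons(orfs)[[id]] - 4L)
    full <- stats::setNames(numeric(length(eligible)),
                            as.character(eligible))
    full[names(counts)] <- counts
    suppressWarnings(stats::chisq.test(full))$p.value
  }, numeric(1))
  # family-wise test over the 10 genes (Bonferroni at alpha = 0.01)
  expect_gt(min(pvals) * length(pvals), 0.01)
})

test_that("an A-site dwell multiplier doubles sampled density", {
  orfs <- buildSyntheticReference(n_orfs = 10L,
                                  length_range_codons = c(80L, 120L),
                                  seed = 31L)
  truth <- setDwell(simulationTruth(orfs, init_peak_prob = 0, seed = 32L),
                    "A", "AAA", 2.0)
  reads <- simulateFootprints(orfs, truth, 4e5)
  # mean per-position count at positions placing AAA in the A site vs rest
  counts <- tapply(reads$count, list(reads$orf_id, reads$psite_index), sum)
  num <- den <- 0
  n_num <- n_den <- 0L
  for (id in orfIds(orfs)) {
    cods <- strsplit(as.character(codingSeqs(orfs)[[id]]), "")[[1]]
    cods <- vapply(seq(1, length(cods) - 2, 3), function(i)
      paste(cods[i:(i + 2)], collapse = ""), character(1))
    for (k in seq.int(3L, nCodons(orfs)[[id]] - 4L)) {
      cnt <- counts[id, as.character(k)]
      if (is.na(cnt)) cnt <- 0
      if (cods[k + 2L] == "AAA") {  # codon k+1 (0-based) in the A site
        num <- num + cnt; n_num <- n_num + 1L
      } else {
        den <- den + cnt; n_den <- n_den + 1L
      }
    }
  }
  ratio <- (num / n_num) / (den / n_den)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("simulated FASTQ output is byte-identical across reruns", {
  orfs <- buildSyntheticReference(n_orfs = 3L,
                                  length_range_codons = c(30L, 40L),
                                  seed = 41L)
  truth <- simulationTruth(orfs, seed = 42L)
  emit <- function() {
    reads <- simulateFootprints(orfs, truth, 500L)
    seqs <- makeReadSequences(orfs, reads, truth, seed = 43L)
    f <- tempfile(fileext = ".fastq")
    writeFootprintFastq(seqs, f)
    f
  }
  f1 <- emit()
  f2 <- emit()
  expect_identical(readLines(f1), readLines(f2))
})

test_that("queue injection follows the binomial stacking model", {
  orfs <- buildSyntheticReference(n_orfs = 5L,
                                  length_range_codons = c(60L, 80L),
                                  seed = 51L)
  truth0 <- simulationTruth(orfs, queue_probability = 0, seed = 52L)
  reads <- simulateFootprints(orfs, truth0, 2e4)
  stalls <- do.call(rbind, lapply(orfIds(orfs), function(id)
    data.frame(orf_id = id, codon_index = 20L)))

  out0 <- injectQueue(reads, truth0, stalls, seed = 53L)
  expect_equal(sum(out0$count), sum(reads$count))

  truth1 <- simulationTruth(orfs, queue_probability = 1, seed = 52L)
  out1 <- injectQueue(reads, truth1, stalls, spacing_nt = 28L, seed = 53L)
  lead <- out1[!out1$queued & paste(out1$orf_id, out1$psite_index + 1L)
               %in% paste(stalls$orf_id, stalls$codon_index), ]
  expect_equal(sum(out1$count[out1$queued]), sum(lead$count))
  # trailing 5' ends sit exactly spacing nt upstream, per length
  q <- out1[out1$queued, ]
  key_lead <- sort(paste(lead$orf_id, lead$fiveprime - 28L, lead$length))
  key_trail <- sort(paste(q$orf_id, q$fiveprime, q$length))
  expect_identical(key_trail, key_lead)

  truth5 <- simulationTruth(orfs, queue_probability = 0.5, seed = 52L)
  big <- simulateFootprints(orfs, truth0, 2e5, seed = 54L)
  outp <- injectQueue(big, truth5, stalls, seed = 55L)
  n_lead <- sum(big$count[paste(big$orf_id, big$psite_index + 1L) %in%
                            paste(stalls$orf_id, stalls$codon_index)])
  n_trail <- sum(outp$count[outp$queued])
  sigma <- sqrt(n_lead * 0.5 * 0.5)
  expect_lt(abs(n_trail - 0.5 * n_lead), 3 * sigma)

  expect_error(injectQueue(reads, truth1,
                           data.frame(orf_id = "nope", codon_index = 1L)),
               "nope")
})

test_that("RNA-seq simulation is uniform and abundance-proportional", {
  coding <- stats::setNames(rep(paste0(
    "ATG", strrep("GCT", 58), "TGA"), 4), paste0("g", 1:4))
  orfs <- OrfSet(coding)
  ab <- stats::setNames(c(1, 1, 1, 1), paste0("g", 1:4))
  rna <- simulateRnaseq(orfs, ab, 2e4, seed = 61L)
  per_gene <- tapply(rna$count, rna$orf_id, sum)
  sigma <- sqrt(2e4 * 0.25 * 0.75)
  expect_true(all(abs(per_gene - 5e3) < 3 * sigma))
  # 5' ends stay inside the valid start range and cover it evenly
  expect_true(all(rna$fiveprime >= 0 & rna$fiveprime <= 3 * 60 - 36))
  pos_counts <- tapply(rna$count, rna$fiveprime, sum)
  gof <- suppressWarnings(stats::chisq.test(pos_counts))
  expect_gt(gof$p.value, 0.001)

  ab0 <- ab; ab0["g3"] <- 0
  rna0 <- simulateRnaseq(orfs, ab0, 1e4, seed = 62L)
  expect_false("g3" %in% rna0$orf_id)

  ab2 <- ab; ab2["g1"] <- 2
  rna2 <- simulateRnaseq(orfs, ab2, 5e4, seed = 63L)
  pg <- tapply(rna2$count, rna2$orf_id, sum)
  expect_gt(pg[["g1"]] / pg[["g2"]], 1.8)
  expect_lt(pg[["g1"]] / pg[["g2"]], 2.2)

  expect_error(simulateRnaseq(orfs, stats::setNames(numeric(0),
                                                    character(0)), 10),
               "empty")
})
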