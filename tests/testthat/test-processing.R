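test_that("poly-A trimming determines footprint length or ambiguity", {
  # coding designed so a 24-nt footprint ends just before a C (clean
  # boundary) and a 25-nt footprint would end on a genomic A (ambiguous)
  body <- paste0(strrep("GCT", 7))             # 21 nt of GCTs
  orfs <- OrfSet(c(g = paste0("ATG", body, "CAT", "GGG", "TGA")),
                 upstream = strrep("T", 60), downstream = strrep("C", 60))
  ref <- as.character(codingSeqs(orfs)[["g"]])

  # layout: positions 1-3 ATG, 4-24 GCTx7, 25-27 CAT, 28-30 GGG, 31-33 TGA
  read_clean <- paste0(substr(ref, 1, 27), "AAAA")  # boundary base G
  expect_equal(substr(ref, 28, 28), "G")
  expect_equal(determineFootprintLength(read_clean, orfs, "g", 0), 27L)

  # 25-nt footprint whose tail begins on the genomic A of CAT: the match
  # extends through that A, so the boundary cannot be placed -> ambiguous
  expect_equal(substr(ref, 26, 26), "A")
  read_amb <- paste0(substr(ref, 1, 25), "AAAA")
  expect_true(is.na(determineFootprintLength(read_amb, orfs, "g", 0)))

  # read matching the reference to its end carries no observable tail
  read_full <- substr(ref, 1, 27)   # ends in T: unambiguous
  expect_equal(determineFootprintLength(read_full, orfs, "g", 0), 27L)
  # ...but a full-length match ending in A cannot place a tail boundary
  read_full_a <- substr(ref, 1, 26)  # ends on the A of CAT
  expect_true(is.na(determineFootprintLength(read_full_a, orfs, "g", 0)))

  expect_error(determineFootprintLength("ATGGC", orfs, "g", 0),
               "21")
  bad <- paste0("TTTTT", substr(ref, 6, 30))
  expect_error(determineFootprintLength(bad, orfs, "g", 0),
               "21-mer")
})

test_that("exact-prefix placement recovers simulated positions", {
  orfs <- buildSyntheticReference(n_orfs = 5L,
                                  length_range_codons = c(40L, 60L),
                                  seed = 71L)
  truth <- simulationTruth(orfs, seed = 72L)
  reads <- simulateFootprints(orfs, truth, 2000L)
  seqs <- makeReadSequences(orfs, reads, truth, seed = 73L)
  fp <- mapFiveprime(seqs, orfs)
  # unambiguous placed reads must reproduce the true (position, length)
  # multiset restricted to unambiguous boundaries
  placed <- sum(fp$count)
  expect_gt(placed, 0.5 * sum(reads$count))
  got <- fp[!is.na(fp$length), ]
  truthtab <- stats::aggregate(count ~ orf_id + fiveprime + length,
                               data = reads, FUN = sum)
  m <- merge(got, truthtab, by = c("orf_id", "fiveprime", "length"))
  # placed unambiguous reads correspond to simulated reads; the rare
  # exception is a tail matching genomic As to the read's very end,
  # which legitimately reports the full read length
  expect_gte(nrow(m), 0.97 * nrow(got))
  expect_true(all(m$count.x <= m$count.y))
})

test_that("A-free boundary contexts yield an ambiguity rate of zero", {
  # body codons over {C,G,T} only, stop TGA, A-free flanks, 28-mers only:
  # no footprint boundary can fall on a genomic A
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  w <- stats::setNames(as.numeric(!grepl("A", sense)), sense)
  orfs <- buildSyntheticReference(
    n_orfs = 4L, length_range_codons = c(40L, 60L),
    codon_usage_weights = w,
    flank_composition = c(A = 0, C = 1, G = 1, T = 1), seed = 81L)
  # force the TGA stop so the only stop-codon A sits at L-1
  coding <- as.character(codingSeqs(orfs))
  coding <- paste0(substr(coding, 1, nchar(coding) - 3), "TGA")
  names(coding) <- orfIds(orfs)
  orfs <- OrfSet(coding, upstream = as.character(upstreamFlank(orfs)),
                 downstream = as.character(downstreamFlank(orfs)))
  truth <- simulationTruth(orfs, length_probs = c("28" = 1), seed = 82L)
  reads <- simulateFootprints(orfs, truth, 3000L)
  seqs <- makeReadSequences(orfs, reads, truth, seed = 83L)
  fp <- mapFiveprime(seqs, orfs)
  expect_equal(sum(fp$count[is.na(fp$length)]), 0)
})

test_that("calibration recovers per-length offsets and flags noise", {
  orfs <- buildSyntheticReference(n_orfs = 10L,
                                  length_range_codons = c(80L, 120L),
                                  seed = 91L)
  truth <- simulationTruth(
    orfs, length_probs = stats::setNames(rep(1 / 7, 7), 25:31),
    seed = 92L)
  reads <- simulateFootprints(orfs, truth, 2e5)
  cal <- calibratePsite(reads, orfs)
  expect_identical(cal@source, "calibrated")
  expect_equal(psiteOffset(cal, 28), c("28" = 12))
  expect_equal(unname(psiteOffset(cal)[as.character(25:31)]),
               c(12, 12, 12, 12, 13, 13, 14))
  expect_equal(frameShift(cal, 31), c("31" = -2))
  expect_equal(frameShift(cal, 28), c("28" = 0))

  # uniform-random 5' ends carry no start-codon peak
  set.seed(93)
  noise <- data.frame(orf_id = sample(orfIds(orfs), 5000, replace = TRUE),
                      fiveprime = sample(-40:100, 5000, replace = TRUE),
                      length = 28L, count = 1L)
  expect_warning(ncal <- calibratePsite(noise, orfs), "failed")
  expect_true(is.na(psiteOffset(ncal, 28)))
  expect_equal(calibrationReport(ncal)$status, "no-peak")
})

test_that("pooling applies frame shifts and conserves counts", {
  orfs <- buildSyntheticReference(n_orfs = 2L,
                                  length_range_codons = c(30L, 40L),
                                  seed = 95L)
  id <- orfIds(orfs)[1]
  fp <- data.frame(orf_id = id,
                   fiveprime = c(-13L, -12L, 0L, 30L),
                   length = c(29L, 28L, 31L, 24L),
                   count = c(1L, 2L, 4L, 8L))
  expect_warning(tr <- poolAndFrameshift(fp, fixedCalibration(), orfs),
                 "25-31")
  # 29-mer at -13 shifted 3'-ward by 1 nt lands with the 28-mers at -12
  expect_equal(trackCount(tr, id, -12), 3)
  # 31-mer at 0 lands at +2
  expect_equal(trackCount(tr, id, 2), 4)
  expect_equal(sum(shiftedTrack(tr, id)), 7)          # 24-mer dropped
  expect_equal(unname(droppedCounts(tr)["bad_length"]), 8)
  # the unsplit layer keeps everything at raw positions
  expect_equal(trackCount(tr, id, 30, layer = "unsplit"), 8)
  expect_equal(sum(unsplitTrack(tr, id)), 15)
})

test_that("calibrated offsets equal simulator truth on jitter-free data", {
  sim <- sharedPerturbationSim()
  truth_off <- attr(sim$wt, "truth")@psite_offset
  cal_off <- psiteOffset(sim$cal)
  for (L in names(cal_off))
    expect_equal(unname(cal_off[L]), unname(as.numeric(truth_off[L])),
                 info = paste("length", L))
})
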