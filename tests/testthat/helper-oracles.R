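# Independent oracles and shared fixtures, built in code at test time.

# Brute-force metacodon window: double loop over instances and window
# positions, reading counts through the public accessor only.
bruteMetacodon <- function(codon, tracks, orfs, edge = 7L, width = 21L) {
  inst <- enumerateCodonInstances(orfs, codon)
  nc <- nCodons(orfs)
  inst <- inst[inst$codon_index >= edge &
                 inst$codon_index < nc[inst$orf_id] - edge, , drop = FALSE]
  raw <- numeric(width)
  for (r in seq_len(nrow(inst))) {
    for (i in seq_len(width)) {
      pos <- inst$start_nt[r] - 21L + (i - 1L)
      raw[i] <- raw[i] + trackCount(tracks, inst$orf_id[r], pos)
    }
  }
  raw
}

# Exact two-sample two-sided K-S p-value by full enumeration over all
# choose(n1+n2, n1) label arrangements of the pooled sample.
ksStatistic <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pooled, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

ksEnumerationP <- function(x, y) {
  d_obs <- ksStatistic(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  hits <- 0L
  for (j in seq_len(ncol(idx))) {
    xi <- pooled[idx[, j]]
    yi <- pooled[-idx[, j]]
    if (ksStatistic(xi, yi) >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(idx)
}

# Exact hypergeometric upper tail by enumeration over all draws of |B|
# from the background, with A fixed.
hyperEnumerationP <- function(size_a, size_b, background_size, overlap) {
  idx <- utils::combn(background_size, size_b)
  # elements 1..size_a are "in A"
  ov <- colSums(idx <= size_a)
  mean(ov >= overlap)
}

# In-frame sliding-window codon scan, independent of enumerateCodonInstances.
scanInstances <- function(coding_seq, codon) {
  L <- nchar(coding_seq)
  hits <- integer(0)
  for (p in seq(1L, L - 2L, by = 3L)) {
    if (substr(coding_seq, p, p + 2L) == codon)
      hits <- c(hits, (p - 1L) %/% 3L)
  }
  hits
}

# Build FootprintTracks directly from a manual sized-5'-end table.
tracksFromTable <- function(fp, orfs) {
  poolAndFrameshift(fp, fixedCalibration(), orfs)
}

# A small ORF with a prescribed codon vector (start/stop added).
orfFromCodons <- function(body_codons, id = "g",
                          up = strrep("C", 60), down = strrep("C", 60)) {
  seqs <- c(paste0("ATG", paste(body_codons, collapse = ""), "TGA"))
  names(seqs) <- id
  OrfSet(seqs, upstream = up, downstream = down)
}

# Shared moderate two-condition simulation (WT null vs A-site VAA x1.5),
# cached for the session so several files can reuse it.
.simCache <- new.env(parent = emptyenv())
sharedPerturbationSim <- function() {
  if (!is.null(.simCache$sim)) return(.simCache$sim)
  orfs <- buildSyntheticReference(n_orfs = 20L,
                                  length_range_codons = c(150L, 250L),
                                  seed = 101L)
  wt_truth <- simulationTruth(orfs, seed = 102L)
  mut_truth <- simulationTruth(orfs, seed = 103L)
  for (cd in c("AAA", "CAA", "GAA"))
    mut_truth <- setDwell(mut_truth, "A", cd, 1.5)
  wt <- simulateFootprints(orfs, wt_truth, 3e5)
  mut <- simulateFootprints(orfs, mut_truth, 3e5)
  cal <- calibratePsite(wt, orfs)
  sim <- list(orfs = orfs,
              wt = wt, mut = mut, cal = cal,
              tracks_wt = poolAndFrameshift(wt, cal, orfs),
              tracks_mut = poolAndFrameshift(mut, cal, orfs))
  .simCache$sim <- sim
  sim
}
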