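---
title: "Codon-resolution analysis of ribosome profiling libraries"
author: "riboDwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-resolution analysis of ribosome profiling libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboDwell)
```

# The problem

Ribosome profiling sequences the ~28-nt mRNA fragments protected by
translating ribosomes.  Because each footprint's 5' end sits a fixed,
length-dependent distance upstream of the codon held in the ribosome's P
site, a deep library resolves ribosome positions at codon resolution: the
relative density of 5' ends at a position is a proxy for the relative
time ribosomes spend there.  `riboDwell` implements the full analytical
chain needed to ask whether a perturbation — for example the loss of a
tRNA anticodon modification — changes how long the ribosome dwells on
specific codons in specific ribosomal sites (E, P, A and their
neighbours), whether any slowdown is strong enough to queue trailing
ribosomes, and whether downstream gene-expression signatures (such as
GCN4-target induction) accompany it.

The package is organised around a synthetic-data-first philosophy: a
seeded footprint simulator with known dwell-time structure generates
libraries for which every downstream answer is known, so each stage of
the pipeline is validated by parameter recovery rather than by eyeball.

# Read anatomy and poly-A ambiguity

Libraries prepared with in-vitro polyadenylation yield reads of the form
*footprint + poly-A tail*.  The footprint length is recovered by
comparing the read to the reference: the length is the number of leading
bases matching the reference before the tail begins
(`determineFootprintLength()`).  When the genomic base at the tail
boundary is itself an A the boundary cannot be placed and the read's
length is *ambiguous*; such reads are excluded from every length-specific
computation but retained in the unsplit pool used for gene-expression
counting.  A read matching the reference to its very end is only
assignable when its final base is not an A; otherwise the unobserved tail
could have begun inside the match and the read is likewise ambiguous.
This exclusion is not cosmetic: around A-rich sequence it carves a
reproducible hole in coverage roughly 10 nt upstream of an A-run's
aligned origin, which the queuing tests reproduce deliberately.

# Coordinate frame

All positions are ORF-relative, 0-based and half-open: position 0 is the
A of the start codon and upstream positions are negative.  Genomic
projection (splicing, strand flips, flank clipping) happens exactly once,
in `loadReference()`; every formula downstream is stated in the ORF
frame.  Count tracks cover `[-60, 3*ncodons + 30)` so that windows of
early and late codons remain inside allocated space.

# P-site calibration

Ribosomes engaged at start codons produce a sharp 5'-end peak whose
distance from position 0 equals the P-site offset for that read length.
`calibratePsite()` builds a per-length metagene over a `[-40, +20]`
window, takes the modal upstream peak as the offset, and derives the
*frame shift* that brings each length into frame with 28-mers
(`shift(L) = offset(28) - offset(L)`; negative values shift 3'-ward).
Defaults: at least 200 reads per length in the window, and a peak at
least 3x the mean off-window background; neither value is dictated by the
underlying method description, so both are exposed as arguments.  Ties in
the peak search are broken toward the expected offset table
(25-28: 12 nt, 29/30: 13 nt, 31: 14 nt), which is also the fixed fallback
table (`fixedCalibration()`) used, with a warning, when a length cannot
be calibrated.  On jitter-free simulated data the calibrated offsets
equal the simulator's configured anatomy exactly, which is one of the
package's acceptance properties.

# Metacodon profiles and bulk occupancy

For a codon with instances at first-nt positions `c`, the metacodon
vector sums frame-shifted 5'-end counts at `c - 21 + i` for
`i = 0..20`.  The 21-nt offset is the 28-mer P-site offset (12 nt) plus
the 9-nt distance from the P-site codon back to the window start, so the
in-frame peaks map to ribosomal sites as
`0:-2, 3:-1, 6:A, 9:P, 12:E, 15:+1, 18:+2`.  Profiles are normalized to
the arithmetic mean of the four *outer-site* peak values (indices 0, 3,
15, 18) — peak values, not whole-window means, because the normalizer is
defined in terms of peak heights; after normalization the outer-peak mean
is exactly 1 and the remaining peak heights are the *bulk codon
occupancies*.  Two design choices here were genuinely open and are fixed
as follows:

* instances within 7 codons of either ORF end are skipped, so the whole
  21-nt window (and the +2-site codon) lies in covered track space;
* amino-acid-pair metaplots (`pairMetaplot()`) extend the window to 24 nt
  to cover both codons and normalize to the outer peaks available in that
  window (indices 0, 3, 18, 21).

Under the simulator's multiplicative dwell model a single-site multiplier
`m` reappears as a bulk occupancy ratio of about `m` (attenuated by a few
per cent because perturbed codons also inflate the genome-wide average
that the outer-site normalizer sees); the recovery tests assert
`m ± 0.1 m` at one million reads.

# Single-codon occupancy and K-S comparison

The occupancy of codon instance *i* of gene *j* in site *k* is the number
of in-frame reads placing that codon in that site divided by the gene's
mean in-frame read density.  In-frame means 5' ends a multiple of 3 nt
from the site's first nt on the frame-shifted track.  The first 4 codons
and codons with no in-frame reads are excluded from both the records and
the denominator; the denominator attributes each in-frame 5' end to its
A-site codon, so numerator and denominator live in one consistent site
frame and uniform coverage yields occupancy exactly 1.  Genome-wide
occupancy distributions per (codon, site) are compared between strains
with the two-sided two-sample Kolmogorov-Smirnov test (`stats::ks.test`),
exact (enumeration) when the smaller sample has at most 10 observations
and asymptotic otherwise; an independent brute-force enumeration oracle
in the test suite pins the exact branch.  The p-value grid is reported
raw — no multiple-testing adjustment — matching the heatmap display
convention; significance calling for expression changes is delegated to
external count-model tools and re-enters as gene lists.

Fold changes between conditions are computed per matched instance (both
conditions must have a record; the joint-missingness rule is not
specified by the method description, so matching is the package's
choice) and binned by WT read coverage in log2 bins of width 0.2.  The
read-support threshold for "confident" changes (default 32 reads) is
applied per condition by default; because the source material states the
rule both as "in both datasets" and "between both datasets", the mode is
configurable (`each`/`combined`) and recorded in output metadata.

# Queuing metaplots

A codon slow enough to matter should stack a trailing ribosome one
footprint width (~28 nt) upstream.  Candidates are AAA/CAA instances with
at least a 2-fold occupancy increase and sufficient reads; around each
candidate the track is normalized by the host ORF's mean per-nt density
over the gene body (the wording "mean read density for the entire ORF" is
used rather than total gene reads — the two differ by a constant per gene
and the density form makes a uniform gene exactly flat at 1), profiles
are summed, and each window position is divided by the number of
candidates whose gene body covers it.  The window `[-45, +30]` nt is the
package's choice (one footprint width upstream plus margin; no window is
printed in the source).  Position 0 corresponds to 5' ends of reads
holding the candidate codon in the A site.  With simulated stacking at
5'-to-5' spacing `s`, the secondary peak sits at exactly `-s` — asserted
for `s` in {26, 28, 30}.

# Expression windows, RPKM and enrichment

Gene-expression counting uses the unsplit pool and the window from 12 nt
upstream of the start codon to 14 nt upstream of the stop codon, with the
first 8 codons excluded; since the 8-codon exclusion applies to all
gene-expression calculations it dominates the upstream pad, giving the
default window `[12, L - 14)` where `L` is the stop codon's first nt.
RPKM is reads per kilobase of ORF window per million ORF-assigned reads.
RNA-seq libraries are counted with the same window rules, keeping
footprint/transcript fold-change comparisons symmetric.  Gene-set
enrichment uses the upper-tail hypergeometric test against an explicit
background (the set of genes with confident expression everywhere —
definable by a configurable filter, since the original filter is not
printed), and a two-sample K-S test of target-set fold changes against
the rest of the genome with group medians reported.

A small analytic helper, `interRibosomeSpacing()`, converts a mean
ribosome density (one ribosome per 164 nt) into the mean inter-ribosome
spacing in codons (~55), the elongation-delay budget a transcript of
average density has before elongation, not initiation, becomes rate
limiting.

# The simulator: what it emulates and what it does not

`simulateFootprints()` draws P-site positions with probability
proportional to gene flux times the product of seven site-specific dwell
multipliers (sites -2..+2), then assigns lengths and 5' ends from the
configured anatomy and appends geometric poly-A tails (>= 4 nt).  Key
design decisions:

* **Multiplicative dwell model.** Adjacent-codon effects on dwell time
  that are additive on times are multiplicative on rates; a product
  across sites is the simplest model with that property, and it makes
  pair-metaplot expectations exact (a 2x P-site and 2x A-site multiplier
  compose to ~4x when both land in one configuration).
* **Initiation-limited sampling.** Positions are sampled independently —
  no explicit ribosome traffic or exclusion — matching the regime where
  initiation is rate limiting.  Queuing is injected explicitly
  (`injectQueue()`), as stacked trailing reads at a configurable
  5'-to-5' spacing, rather than emergent from a traffic model (a TASEP
  simulation is out of scope).
* **Start-codon enrichment.** A configurable fraction of reads
  (default 5%, `init_peak_prob`) is drawn with the start codon in the P
  site, emulating the initiation peak of cycloheximide-treated libraries;
  calibration needs it, and real libraries always show it.
* **Deterministic anatomy.** 5' ends are deterministic given length
  (offsets 12/12/12/12/13/13/14 nt for 25-31-mers); an optional ±1-nt
  jitter flag exercises robustness without changing defaults.
* **Instance-level stalls.** Besides codon-level multipliers, designated
  individual codon instances can be stalled (`stall_sites`), which is the
  ground truth the queuing candidate-selection tests need.

Defaults were chosen once to mirror a typical yeast Ribo-seq experiment:
length distribution peaked at 28 nt over 25-31 nt, equal gene fluxes
unless specified, uniform codon usage in synthetic references, geometric
tails.  What the simulator deliberately does **not** emulate: sequencing
errors, rRNA contamination, multimapping beyond exact 21-mer collisions,
UMI structure, nuclease sequence bias, and emergent ribosome traffic.
Passing tests therefore demonstrate correctness of the *analytical*
chain, not robustness to every artifact of real libraries; with real
data, alignment and rRNA filtering are expected to happen upstream, and
mapped 5'-end tables enter through `readFiveprimeTable()`.

# Numerical choices and degenerate inputs

* Outer-peak mean of zero: the raw profile is returned and normalization
  is flagged `NA` rather than erroring, so a sparse codon does not kill a
  whole table.
* Zero-density genes contribute no occupancy records and are counted.
* K-S cells with an empty sample are `NA` in the grid.
* Ambiguous lengths are `NA` throughout and serialized as `"AMB"`.
* All aggregation is integer-count based; no pseudocounts anywhere.
* Every stochastic entry point takes an explicit seed and reruns are
  byte-identical; the pipeline writes its configuration and a manifest
  with row counts and a configuration hash.

# Problem sizes

The shipped test-suite and acceptance runs use synthetic references of
10-50 genes of 60-280 codons and libraries of 1e4 to 1e6 footprints —
sizes at which every recovery bound in the suite (offset exactness, bulk
ratios within ±10%, K-S ranking of perturbed codons, queue-peak position
exactness) is comfortably met on a single CPU in seconds to a couple of
minutes.

# Known limitations

* Calibration requires a visible start-codon peak; libraries without
  initiation enrichment must fall back to the fixed offset table.
* The ambiguity rule assumes the tail is pure poly-A; sequencing errors
  inside tails would leak mis-sized reads in real data.
* Overlapping ORFs are counted independently per ORF, the simplest
  reproducible convention; no attempt is made to deconvolve shared reads.
* The K-S comparison treats instances as exchangeable; gene-level
  covariance (e.g. shared denominators within a gene) is not modelled.
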