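# riboDwell

Codon-resolution analysis of ribosome profiling (Ribo-seq) libraries:
P-site offset calibration, metacodon profiles and bulk codon occupancy,
single-codon occupancy with Kolmogorov–Smirnov comparison between
strains, ribosome-queuing metaplots, ORF-windowed expression (RPKM) with
gene-set enrichment — plus a seeded synthetic footprint simulator with
known dwell-time structure that provides ground truth for every stage.

## The science

A translating ribosome protects a ~28-nt mRNA footprint whose 5′ end
lies a fixed, length-dependent distance upstream of the P-site codon
(12 nt for 25–28-mers, 13 nt for 29/30-mers, 14 nt for 31-mers).  After
shifting every read length into the 28-mer frame, the density of 5′ ends
reports how long ribosomes dwell with each codon in each ribosomal site.
The package computes:

* **Bulk codon occupancy** — align all in-frame instances of codon
  *NNN*; the metacodon vector is
  `raw[i] = Σ_instances counts(c − 21 + i)`, `i = 0..20`, with peaks
  mapping to sites `0:−2, 3:−1, 6:A, 9:P, 12:E, 15:+1, 18:+2`;
  normalized to the mean outer-site peak (indices 0, 3, 15, 18), the
  peak heights are the bulk occupancies per site.
* **Single-codon occupancy** — for codon *i* of gene *j* in site *k*,
  `O(i,j,k) = (in-frame reads placing the codon in site k) /
  (gene mean in-frame read density)`, excluding the first 4 codons and
  codons with no in-frame reads; genome-wide distributions per
  (codon, site) are compared between strains by two-sample K-S test
  (exact for small samples).
* **Queuing** — around high-occupancy AAA/CAA instances (fold ≥ 2,
  ≥ 32 reads), ORF-density-normalized metaplots reveal stacked trailing
  ribosomes as a secondary peak one footprint width (~28 nt) upstream.
* **Expression** — reads per kilobase of ORF window per million ORF
  reads, counted from 12 nt upstream of the start to 14 nt upstream of
  the stop with the first 8 codons excluded; hypergeometric gene-set
  overlap and target-set K-S enrichment on fold changes.

Libraries built with in-vitro polyadenylation carry poly-A tails; reads
whose tail boundary falls on a genomic A have ambiguous length and are
excluded from length-specific analyses (kept in the unsplit pool used
for expression counting).

## Worked example

Simulate a wild-type library and a mutant in which the ribosome dwells
1.5× longer with AAA in the A site, calibrate P-site offsets from the
start-codon metagene, and recover the perturbation:

```r
library(riboDwell)

orfs <- buildSyntheticReference(n_orfs = 20,
                                length_range_codons = c(150, 250),
                                seed = 1)
wt_truth  <- simulationTruth(orfs, seed = 2)
mut_truth <- setDwell(simulationTruth(orfs, seed = 3), "A", "AAA", 1.5)
wt  <- simulateFootprints(orfs, wt_truth,  3e5)
mut <- simulateFootprints(orfs, mut_truth, 3e5)

(cal <- calibratePsite(wt, orfs))
#> PsiteCalibration (calibrated)
#>   length : 25   26   27   28   29   30   31
#>   offset :   12   12   12   12   13   13   14
#>   shift  :    0    0    0    0   -1   -1   -2

tw <- poolAndFrameshift(wt,  cal, orfs)
tm <- poolAndFrameshift(mut, cal, orfs)
ch <- occupancyChange(assembleBulkTable(tm, orfs, sample_id = "mut"),
                      assembleBulkTable(tw, orfs, sample_id = "wt"))
subset(ch, site == "A" & codon %in% c("AAA", "CAA", "GAA"))[,
       c("codon", "site", "ratio")]
#>     codon site     ratio
#> 5     AAA    A 1.4245715
#> 117   CAA    A 1.0177779
#> 229   GAA    A 0.9732406

ow <- singleCodonOccupancy(tw, orfs, "A")
om <- singleCodonOccupancy(tm, orfs, "A")
ksCompare(om, ow, "AAA", "A")
#>   codon site D_statistic p_value n1 n2
#> 1   AAA    A   0.9142857       0 70 70
ksCompare(om, ow, "CAA", "A")
#>   codon site D_statistic p_value n1 n2
#> 1   CAA    A  0.09859155 0.88048 71 71
```

The perturbed codon's bulk occupancy ratio comes back near 1.5 (the
outer-site normalizer absorbs a few per cent), its occupancy
distribution shifts decisively (K-S p ≈ 0), and unperturbed codons stay
at ratio ≈ 1 with null p-values.

An end-to-end pipeline over all stages, with TSV artifacts, a manifest
and a log, is available as `runPipeline("all", out_dir = "run1",
seed = 5)` or from the shell via `inst/scripts/ribodwell`.

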