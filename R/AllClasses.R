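#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom Biostrings DNAStringSet
NULL

## Ribosomal site labels follow the metacodon peak mapping
## (window index 0 -> site -2, 3 -> -1, 6 -> A, 9 -> P, 12 -> E,
##  15 -> +1, 18 -> +2), listed here 5' to 3' along the footprint.
.SITE_NAMES <- c("-2", "-1", "A", "P", "E", "+1", "+2")

## Distance (nt) from a frame-shifted 5' end to the first nt of the codon
## occupying each site, in the 28-mer frame (P-site offset 12 nt).
.SITE_OFFSETS <- c("-2" = 21L, "-1" = 18L, "A" = 15L, "P" = 12L,
                   "E" = 9L, "+1" = 6L, "+2" = 3L)

## Codon index of the codon in each site, relative to the P-site codon.
.SITE_DELTAS <- c("-2" = 3L, "-1" = 2L, "A" = 1L, "P" = 0L,
                  "E" = -1L, "+1" = -2L, "+2" = -3L)

## Fixed per-length P-site offsets (5' end -> first nt of P-site codon):
## 25-28-mers share the 12-nt offset; 29/30-mers 13 nt; 31-mers 14 nt.
## Equivalent frame shifts into the 28-mer frame: 0,0,0,0,-1,-1,-2.
.FIXED_OFFSETS <- c("25" = 12L, "26" = 12L, "27" = 12L, "28" = 12L,
                    "29" = 13L, "30" = 13L, "31" = 14L)

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.allCodons <- function() {
    b <- c("A", "C", "G", "T")
    as.vector(outer(outer(b, b, paste0), b, paste0))
}

.senseCodons <- function() {
    setdiff(.allCodons(), .STOP_CODONS)
}

#' OrfSet: a set of open reading frames with flanks
#'
#' Container for ORF coding sequences in the ORF-relative coordinate frame:
#' position 0 is the A of the start codon, positions increase 3'-ward and
#' upstream positions are negative.  Each ORF carries its spliced coding
#' sequence (start codon through stop codon, reverse-complemented for
#' minus-strand genes at load time) and up/downstream genomic flanks.
#'
#' @slot coding \code{DNAStringSet} of coding sequences, named by ORF id.
#' @slot upstream \code{DNAStringSet} of 5' flanks (coding strand).
#' @slot downstream \code{DNAStringSet} of 3' flanks (coding strand).
#' @slot placement \code{DataFrame} of optional genomic placement
#'   (chrom, strand, block_starts, block_ends as comma-joined 0-based
#'   half-open coordinates); zero rows when unplaced.
#' @slot flagged logical; \code{TRUE} for ORFs violating the coding-sequence
#'   invariants (length a multiple of 3, ATG start, stop end).  Flagged
#'   models are tolerated (external annotations are imperfect) but marked.
#'
#' @exportClass OrfSet
setClass("OrfSet",
    slots = c(coding = "DNAStringSet",
              upstream = "DNAStringSet",
              downstream = "DNAStringSet",
              placement = "DataFrame",
              flagged = "logical"))

setValidity("OrfSet", function(object) {
    n <- length(object@coding)
    msg <- character()
    if (length(object@upstream) != n || length(object@downstream) != n)
        msg <- c(msg, "flank sets must match the coding set in length")
    if (length(object@flagged) != n)
        msg <- c(msg, "'flagged' must have one entry per ORF")
    ids <- names(object@coding)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "ORF ids must be unique and non-NULL")
    w <- Biostrings::width(object@coding)
    bad <- (w == 0L | w %% 3L != 0L) & !object@flagged
    if (any(bad))
        msg <- c(msg, paste0("unflagged ORFs with length not a positive ",
                             "multiple of 3: ",
                             paste(ids[bad], collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct an OrfSet
#'
#' Validates the coding-sequence invariants (positive multiple-of-3 length,
#' ATG start, TAA/TAG/TGA end) and flags, with a warning, any ORF that
#' violates them.
#'
#' @param coding named \code{DNAStringSet} (or named character) of coding
#'   sequences, start codon through stop codon.
#' @param upstream,downstream flank sequences on the coding strand, in the
#'   same order; defaults to empty flanks.
#' @param placement optional \code{DataFrame} of genomic placement.
#' @return An \code{OrfSet}, ordered by ORF id.
#' @examples
#' orfs <- OrfSet(c(tiny = "ATGAAATAA"))
#' nCodons(orfs)
#' @export
OrfSet <- function(coding, upstream = NULL, downstream = NULL,
                   placement = NULL) {
    coding <- Biostrings::DNAStringSet(coding)
    n <- length(coding)
    if (is.null(upstream))
        upstream <- Biostrings::DNAStringSet(rep("", n))
    if (is.null(downstream))
        downstream <- Biostrings::DNAStringSet(rep("", n))
    upstream <- Biostrings::DNAStringSet(upstream)
    downstream <- Biostrings::DNAStringSet(downstream)
    if (is.null(placement))
        placement <- S4Vectors::DataFrame()
    ids <- names(coding)
    ord <- order(ids)
    coding <- coding[ord]
    upstream <- upstream[ord]
    downstream <- downstream[ord]
    names(upstream) <- names(coding)
    names(downstream) <- names(coding)
    if (nrow(placement) == n)
        placement <- placement[ord, , drop = FALSE]
    cs <- as.character(coding)
    w <- nchar(cs)
    flagged <- w == 0L | w %% 3L != 0L |
        substr(cs, 1L, 3L) != "ATG" |
        !(substr(cs, w - 2L, w) %in% .STOP_CODONS)
    if (any(flagged))
        warning("flagging ", sum(flagged),
                " ORF(s) violating coding-sequence invariants: ",
                paste(utils::head(names(coding)[flagged], 5L),
                      collapse = ", "))
    new("OrfSet", coding = coding, upstream = upstream,
        downstream = downstream, placement = placement, flagged = flagged)
}

#' Simulation ground truth for synthetic footprint libraries
#'
#' Holds every generative parameter of the footprint simulator: per-gene
#' initiation flux, per-site codon dwell multipliers, the footprint length
#' distribution, the per-length P-site offsets (the read anatomy), the
#' poly-A tail model, queuing and start-codon enrichment probabilities, and
#' the seed.  The dwell model is multiplicative across the seven sites
#' (-2, -1, E, P, A, +1, +2): the sampling weight of a P-site position is
#' the gene flux times the product of the multipliers of the seven codons
#' occupying the sites.
#'
#' @slot gene_flux named positive numeric, one per ORF.
#' @slot dwell numeric matrix, rows = sites, columns = codons; default 1.
#' @slot length_probs named probability vector over footprint lengths.
#' @slot psite_offset named integer map, length -> nt from the 5' end to
#'   the first nt of the P-site codon.
#' @slot tail_lengths,tail_probs poly-A tail length distribution (>= 4 nt).
#' @slot queue_probability probability that a read at a stall position
#'   carries a stacked trailing ribosome (used by \code{injectQueue}).
#' @slot init_peak_prob fraction of reads drawn with the start codon in the
#'   P site, emulating the start-codon enrichment of CHX-treated libraries.
#' @slot seed integer seed recorded with the truth.
#'
#' @exportClass SimulationTruth
setClass("SimulationTruth",
    slots = c(gene_flux = "numeric", dwell = "matrix",
              length_probs = "numeric", psite_offset = "numeric",
              tail_lengths = "integer", tail_probs = "numeric",
              queue_probability = "numeric", init_peak_prob = "numeric",
              seed = "integer"))

setValidity("SimulationTruth", function(object) {
    msg <- character()
    if (any(object@gene_flux < 0) || all(object@gene_flux == 0))
        msg <- c(msg, "gene_flux must be non-negative with positive total")
    if (any(object@dwell <= 0))
        msg <- c(msg, "dwell multipliers must be positive")
    if (abs(sum(object@length_probs) - 1) > 1e-8)
        msg <- c(msg, "length_probs must sum to 1")
    used <- names(object@length_probs)[object@length_probs > 0]
    if (!all(used %in% names(object@psite_offset)))
        msg <- c(msg, "psite_offset must cover every length with mass")
    if (any(object@tail_lengths < 4L))
        msg <- c(msg, "poly-A tails are at least 4 nt")
    if (length(msg)) msg else TRUE
})

#' Per-read-length P-site calibration
#'
#' Maps each footprint length to (i) the P-site offset, the distance in nt
#' from the 5' end to the first nt of the P-site codon, and (ii) the frame
#' shift that brings 5' ends of that length into frame with 28-mer reads
#' (negative values shift 3'-ward).  By definition the 28-mer frame shift
#' is 0.  \code{source} records whether the map was calibrated from a
#' start-codon metagene or taken from the fixed reference table.
#'
#' @slot offsets named numeric, length -> P-site offset (NA = failed).
#' @slot frame_shifts named numeric, length -> nt shift into 28-mer frame.
#' @slot source "calibrated" or "fixed-table".
#' @slot report per-length calibration diagnostics (peak position, peak
#'   and background counts, read totals, status).
#'
#' @exportClass PsiteCalibration
setClass("PsiteCalibration",
    slots = c(offsets = "numeric", frame_shifts = "numeric",
              source = "character", report = "data.frame"))

setValidity("PsiteCalibration", function(object) {
    msg <- character()
    fs28 <- object@frame_shifts["28"]
    if (!is.na(fs28) && fs28 != 0)
        msg <- c(msg, "the 28-mer frame shift must be 0")
    ok <- !is.na(object@offsets)
    if (any(object@offsets[ok] < 0))
        msg <- c(msg, "offsets must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Pooled, frame-shifted 5'-end count tracks
#'
#' Per-ORF vectors of footprint 5'-end counts over ORF-relative positions
#' [-pad_up, 3*ncodons + pad_down).  Two layers are kept: \code{shifted}
#' (length-split reads 25-31 nt pooled after the per-length frame shift
#' into the 28-mer frame; ambiguous-length reads excluded) used by all
#' codon-level analyses, and \code{unsplit} (every read at its raw 5' end,
#' ambiguous lengths included) used by gene-expression counting.
#'
#' @slot shifted,unsplit named lists of numeric count vectors.
#' @slot orf_ncodons named integer, codons per ORF (stop included).
#' @slot pad_up,pad_down integer track padding in nt.
#' @slot dropped named numeric totals of discarded records by reason.
#' @slot totals named numeric: total counts per layer.
#'
#' @exportClass FootprintTracks
setClass("FootprintTracks",
    slots = c(shifted = "list", unsplit = "list",
              orf_ncodons = "integer", pad_up = "integer",
              pad_down = "integer", dropped = "numeric",
              totals = "numeric"))

setValidity("FootprintTracks", function(object) {
    msg <- character()
    ids <- names(object@orf_ncodons)
    if (!identical(names(object@shifted), ids) ||
        !identical(names(object@unsplit), ids))
        msg <- c(msg, "track layers must be named consistently")
    explen <- object@pad_up + 3L * object@orf_ncodons + object@pad_down
    if (any(lengths(object@shifted) != explen))
        msg <- c(msg, "shifted track lengths inconsistent with ORF sizes")
    if (any(unlist(object@shifted, use.names = FALSE) < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Metacodon profile
#'
#' The 21-position (24 for amino-acid pairs) vector of pooled frame-shifted
#' 5'-end counts around all in-frame instances of a codon, at window
#' positions c - 21 + i for instance first-nt c and i = 0..20.  Peaks map
#' to ribosomal sites as 0:-2, 3:-1, 6:A, 9:P, 12:E, 15:+1, 18:+2; the
#' normalized vector divides by the mean of the four outer-site peaks
#' (indices 0, 3, 15, 18) so their mean is exactly 1.
#'
#' @slot codon the codon (or amino-acid pair label).
#' @slot raw,normalized numeric window vectors (normalized may be NA when
#'   the outer-peak mean is zero).
#' @slot n_instances number of codon instances contributing.
#' @slot site_map named integer, site label -> 0-based window index.
#' @slot outer_sites integer 0-based window indices of the outer-site
#'   peaks used as the normalizer.
#' @slot window_offset nt from the instance first nt back to window
#'   index 0 (21).
#'
#' @exportClass MetacodonProfile
setClass("MetacodonProfile",
    slots = c(codon = "character", raw = "numeric", normalized = "numeric",
              n_instances = "integer", site_map = "integer",
              outer_sites = "integer", window_offset = "integer"))

setValidity("MetacodonProfile", function(object) {
    msg <- character()
    if (any(object@raw < 0))
        msg <- c(msg, "raw counts must be non-negative")
    if (!all(is.na(object@normalized))) {
        outer_mean <- mean(object@normalized[object@outer_sites + 1L])
        if (abs(outer_mean - 1) > 1e-8)
            msg <- c(msg, "normalized outer-peak mean must equal 1")
    }
    if (length(msg)) msg else TRUE
})
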