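#' @include AllClasses.R
NULL

#' Accessors for OrfSet
#'
#' @param x an \code{OrfSet}.
#' @return \code{orfIds}: character ids; \code{codingSeqs},
#'   \code{upstreamFlank}, \code{downstreamFlank}: \code{DNAStringSet};
#'   \code{nCodons}: named integer (stop codon included);
#'   \code{isFlagged}: named logical.
#' @name OrfSet-accessors
NULL

#' @rdname OrfSet-accessors
#' @export
orfIds <- function(x) names(x@coding)

#' @rdname OrfSet-accessors
#' @export
codingSeqs <- function(x) x@coding

#' @rdname OrfSet-accessors
#' @export
upstreamFlank <- function(x) x@upstream

#' @rdname OrfSet-accessors
#' @export
downstreamFlank <- function(x) x@downstream

#' @rdname OrfSet-accessors
#' @export
nCodons <- function(x) {
    n <- Biostrings::width(x@coding) %/% 3L
    names(n) <- orfIds(x)
    n
}

#' @rdname OrfSet-accessors
#' @export
isFlagged <- function(x) {
    f <- x@flagged
    names(f) <- orfIds(x)
    f
}

#' @describeIn OrfSet-accessors number of ORFs.
#' @export
setMethod("length", "OrfSet", function(x) length(x@coding))

#' @describeIn OrfSet-accessors subset by index or ORF id.
#' @param i index or ORF id.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "OrfSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, orfIds(x))
    pl <- x@placement
    if (nrow(pl)) pl <- pl[i, , drop = FALSE]
    new("OrfSet", coding = x@coding[i], upstream = x@upstream[i],
        downstream = x@downstream[i], placement = pl,
        flagged = x@flagged[i])
})

setMethod("show", "OrfSet", function(object) {
    n <- length(object)
    cat("OrfSet with", n, "ORF(s)\n")
    if (n) {
        nc <- nCodons(object)
        cat("  codons per ORF:", min(nc), "-", max(nc), "\n")
        cat("  flagged (invariant violations):", sum(object@flagged), "\n")
        cat("  flank widths: up",
            paste(range(Biostrings::width(object@upstream)), collapse = "-"),
            "/ down",
            paste(range(Biostrings::width(object@downstream)), collapse = "-"),
            "nt\n")
    }
    invisible(NULL)
})

## coding-strand sequence with flanks; ORF position p sits at string index
## p + width(upstream) + 1
.extendedSeq <- function(orfs, id) {
    i <- match(id, orfIds(orfs))
    paste0(as.character(orfs@upstream[[i]]),
           as.character(orfs@coding[[i]]),
           as.character(orfs@downstream[[i]]))
}

## character vector of an ORF's codons, in order
.orfCodons <- function(orfs, id) {
    s <- as.character(orfs@coding[match(id, orfIds(orfs))])
    L <- nchar(s)
    substring(s, seq(1L, L - 2L, 3L), seq(3L, L, 3L))
}

#' Accessors for PsiteCalibration
#'
#' @param x a \code{PsiteCalibration}.
#' @param length footprint length(s); default all known.
#' @return named numeric offsets / frame shifts (nt).
#' @name PsiteCalibration-accessors
NULL

#' @rdname PsiteCalibration-accessors
#' @export
psiteOffset <- function(x, length = NULL) {
    if (is.null(length)) x@offsets else x@offsets[as.character(length)]
}

#' @rdname PsiteCalibration-accessors
#' @export
frameShift <- function(x, length = NULL) {
    if (is.null(length)) x@frame_shifts
    else x@frame_shifts[as.character(length)]
}

#' @rdname PsiteCalibration-accessors
#' @export
calibrationReport <- function(x) x@report

setMethod("show", "PsiteCalibration", function(object) {
    cat("PsiteCalibration (", object@source, ")\n", sep = "")
    cat("  length :", format(names(object@offsets), width = 4), "\n")
    cat("  offset :", format(object@offsets, width = 4), "\n")
    cat("  shift  :", format(object@frame_shifts, width = 4), "\n")
    invisible(NULL)
})

#' Accessors for FootprintTracks
#'
#' \code{shiftedTrack}/\code{unsplitTrack} return one ORF's count vector;
#' its names are ORF-relative positions.  \code{trackCount} reads counts at
#' given ORF-relative positions (0 outside the padded range).
#'
#' @param x a \code{FootprintTracks}.
#' @param orf_id one ORF id.
#' @param positions integer ORF-relative positions.
#' @param layer "shifted" or "unsplit".
#' @name FootprintTracks-accessors
NULL

#' @rdname FootprintTracks-accessors
#' @export
shiftedTrack <- function(x, orf_id) {
    tr <- x@shifted[[orf_id]]
    if (is.null(tr)) stop("no track for ORF '", orf_id, "'")
    tr
}

#' @rdname FootprintTracks-accessors
#' @export
unsplitTrack <- function(x, orf_id) {
    tr <- x@unsplit[[orf_id]]
    if (is.null(tr)) stop("no track for ORF '", orf_id, "'")
    tr
}

#' @rdname FootprintTracks-accessors
#' @export
trackCount <- function(x, orf_id, positions, layer = c("shifted", "unsplit")) {
    layer <- match.arg(layer)
    tr <- if (layer == "shifted") shiftedTrack(x, orf_id)
          else unsplitTrack(x, orf_id)
    idx <- positions + x@pad_up + 1L
    out <- numeric(length(positions))
    ok <- idx >= 1L & idx <= length(tr)
    out[ok] <- tr[idx[ok]]
    out
}

#' @rdname FootprintTracks-accessors
#' @export
droppedCounts <- function(x) x@dropped

setMethod("show", "FootprintTracks", function(object) {
    cat("FootprintTracks over", length(object@orf_ncodons), "ORF(s)\n")
    cat("  pad: -", object@pad_up, " / +", object@pad_down, " nt\n", sep = "")
    cat("  totals: shifted ", object@totals["shifted"],
        ", unsplit ", object@totals["unsplit"], "\n", sep = "")
    if (any(object@dropped > 0))
        cat("  dropped:",
            paste(names(object@dropped), object@dropped, sep = "=",
                  collapse = ", "), "\n")
    invisible(NULL)
})

#' Accessors for MetacodonProfile
#'
#' @param x a \code{MetacodonProfile}.
#' @name MetacodonProfile-accessors
NULL

#' @rdname MetacodonProfile-accessors
#' @export
rawProfile <- function(x) x@raw

#' @rdname MetacodonProfile-accessors
#' @export
normalizedProfile <- function(x) x@normalized

#' @rdname MetacodonProfile-accessors
#' @export
nInstances <- function(x) x@n_instances

setMethod("show", "MetacodonProfile", function(object) {
    cat("MetacodonProfile for ", object@codon, " (",
        object@n_instances, " instances)\n", sep = "")
    if (all(is.na(object@normalized))) {
        cat("  normalization unavailable (zero outer-peak mean)\n")
    } else {
        h <- object@normalized[object@site_map + 1L]
        cat("  site heights:\n")
        print(round(stats::setNames(h, names(object@site_map)), 3))
    }
    invisible(NULL)
})

setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth:", length(object@gene_flux), "genes, seed",
        object@seed, "\n")
    perturbed <- sum(object@dwell != 1)
    cat("  dwell multipliers != 1:", perturbed, "\n")
    cat("  lengths:", paste(names(object@length_probs)[
        object@length_probs > 0], collapse = ","), "\n")
    cat("  queue p:", object@queue_probability,
        " init peak p:", object@init_peak_prob, "\n")
    invisible(NULL)
})
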