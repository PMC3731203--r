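#' @include AllClasses.R accessors.R occupancy.R
NULL

#' Queuing analysis configuration
#'
#' Candidate stall sites are codon instances (default AAA/CAA, the
#' lysine/glutamine codons read by the modification-dependent tRNAs) whose
#' occupancy increased at least \code{fold_min}-fold with at least
#' \code{reads_min} reads, around which upstream density is metaplotted to
#' look for a stacked trailing ribosome one footprint width (~28 nt)
#' upstream.
#'
#' @param codon_set codons eligible as stall candidates.
#' @param fold_min minimum occupancy fold increase (default 2).
#' @param reads_min read-support threshold (default 32).
#' @param reads_min_mode "each" (both conditions) or "combined" (sum).
#' @param window metaplot window in nt around the A-site-aligned origin.
#' @return A list of class "QueuingConfig".
#' @export
queuingConfig <- function(codon_set = c("AAA", "CAA"), fold_min = 2,
                          reads_min = 32L,
                          reads_min_mode = c("each", "combined"),
                          window = c(-45L, 30L)) {
    if (fold_min <= 1) stop("fold_min must exceed 1")
    if (reads_min < 1L) stop("reads_min must be at least 1")
    structure(list(codon_set = codon_set, fold_min = fold_min,
                   reads_min = as.integer(reads_min),
                   reads_min_mode = match.arg(reads_min_mode),
                   window = as.integer(window)),
              class = "QueuingConfig")
}

#' Select queuing candidate codon instances
#'
#' @param fold_changes matched instance table (the \code{instances}
#'   element of \code{foldChangeVsCoverage}, A-site records).
#' @param config a \code{queuingConfig}.
#' @return The candidate subset (orf_id, codon_index, codon, fold_change,
#'   read support); empty with a warning when nothing qualifies.
#' @export
selectCandidates <- function(fold_changes, config = queuingConfig()) {
    fc <- fold_changes
    pass_reads <- if (config$reads_min_mode == "each")
        fc$numerator_reads_mut >= config$reads_min &
            fc$numerator_reads_wt >= config$reads_min
    else fc$numerator_reads_mut + fc$numerator_reads_wt >=
        config$reads_min
    keep <- fc$codon %in% config$codon_set &
        fc$fold_change >= config$fold_min & pass_reads
    out <- fc[keep, , drop = FALSE]
    rownames(out) <- NULL
    if (!nrow(out))
        warning("no codon instance passes the queuing candidate filters")
    attr(out, "reads_min_mode") <- config$reads_min_mode
    out
}

#' Queuing metaplot around candidate stall sites
#'
#' For each candidate, track counts at window positions around the origin
#' (0 = 5' ends of reads holding the codon in the A site, i.e. position
#' codon_start - 15 on the frame-shifted track) are divided by the host
#' ORF's mean per-nt read density over the gene body; these normalized
#' profiles are summed and each position is divided by the number of
#' candidates whose host gene body covers it.  Ambiguous-length reads are
#' absent from the shifted track by construction, which is what produces
#' the documented depletion of density around -10 nt over A-rich
#' sequence.  A stacked trailing ribosome appears as a secondary peak one
#' footprint width (~28 nt) upstream of the origin.
#'
#' @param candidates table from \code{selectCandidates}.
#' @param tracks the condition to metaplot (typically the mutant)
#'   as \code{FootprintTracks}.
#' @param orfs the matching \code{OrfSet}.
#' @param config a \code{queuingConfig}.
#' @return data.frame (position, mean_density, n_genes); candidates whose
#'   whole window lies outside their gene body are dropped with a
#'   warning.  Normalization metadata are stored in attribute
#'   "normalization".
#' @export
queuingMetaplot <- function(candidates, tracks, orfs,
                            config = queuingConfig()) {
    if (!nrow(candidates)) stop("candidate set is empty")
    w <- seq(config$window[1], config$window[2])
    nc <- nCodons(orfs)
    pad <- tracks@pad_up
    total <- numeric(length(w))
    denom <- numeric(length(w))
    dropped <- 0L
    for (i in seq_len(nrow(candidates))) {
        id <- candidates$orf_id[i]
        L <- 3L * nc[[id]]
        tr <- shiftedTrack(tracks, id)
        body <- tr[(pad + 1L):(pad + L)]
        mean_dens <- sum(body) / L
        if (mean_dens == 0) next
        origin <- 3L * candidates$codon_index[i] - 15L
        pos <- origin + w
        covered <- pos >= 0L & pos < L
        if (!any(covered)) {
            dropped <- dropped + 1L
            next
        }
        vals <- numeric(length(w))
        vals[covered] <- tr[pos[covered] + pad + 1L] / mean_dens
        total <- total + vals
        denom <- denom + as.numeric(covered)
    }
    if (dropped > 0L)
        warning(dropped, " candidate(s) dropped: window outside gene body")
    mean_density <- ifelse(denom > 0, total / denom, NA_real_)
    out <- data.frame(position = w, mean_density = mean_density,
                      n_genes = denom)
    attr(out, "normalization") <-
        "per-candidate mean per-nt ORF density (gene body)"
    out
}

#' Largest upstream secondary peak of a queuing metaplot
#'
#' @param metaplot table from \code{queuingMetaplot}.
#' @param exclude_nt positions within this distance of the origin are
#'   excluded so the primary stall peak is not picked up (default 5).
#' @return Named numeric: the upstream peak offset as a positive distance
#'   in nt, and its height.
#' @export
upstreamPeak <- function(metaplot, exclude_nt = 5L) {
    up <- metaplot[metaplot$position < -exclude_nt &
                   !is.na(metaplot$mean_density), ]
    if (!nrow(up)) stop("no upstream positions in the metaplot")
    i <- which.max(up$mean_density)
    c(offset_nt = -up$position[i], height = up$mean_density[i])
}
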