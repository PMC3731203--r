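#' @include AllClasses.R accessors.R reference.R
NULL

#' Determine footprint length under poly-A ambiguity
#'
#' Libraries are built by in-vitro polyadenylation, so a read is the
#' footprint followed by a poly-A tail.  The footprint length is the
#' number of leading nucleotides matching the reference before the tail
#' begins.  When the genomic base preceding the first observed tail
#' mismatch is an A, the tail boundary cannot be placed (the tail extends
#' the match through genomic As) and the length is ambiguous, encoded as
#' \code{NA}.  A read matching the reference to its full length carries no
#' observable tail and its footprint length is the read length, unless it
#' ends in A (the unobserved tail could have begun inside the match).
#'
#' @param read_sequence character read (footprint + tail).
#' @param orfs an \code{OrfSet}.
#' @param orf_id host ORF.
#' @param candidate_fiveprime ORF-relative 5'-end position of the read.
#' @return Integer footprint length, or \code{NA} for ambiguous.
#' @examples
#' orfs <- OrfSet(c(g = paste0("ATGGCTTTCCGA", "ATGAAATAA")),
#'                downstream = "CCCCCC")
#' # boundary base C -> unambiguous length 9
#' determineFootprintLength("ATGGCTTTCAAAA", orfs, "g", 0)
#' @export
determineFootprintLength <- function(read_sequence, orfs, orf_id,
                                     candidate_fiveprime) {
    if (nchar(read_sequence) < 21L)
        stop("reads shorter than 21 nt cannot be placed")
    ext <- .extendedSeq(orfs, orf_id)
    pad <- Biostrings::width(orfs@upstream)[match(orf_id, orfIds(orfs))]
    start <- candidate_fiveprime + pad + 1L
    if (start < 1L) stop("5' end lies upstream of the available flank")
    ref <- substr(ext, start, start + nchar(read_sequence) - 1L)
    .lengthFromComparison(read_sequence, ref)
}

## core trimming rule shared by the scalar and table interfaces; 'ref' is
## the reference slice aligned at the read's 5' end, same length as 'read'
.lengthFromComparison <- function(read, ref) {
    r <- charToRaw(read)
    g <- charToRaw(substr(ref, 1L, nchar(read)))
    if (length(g) < length(r))
        g <- c(g, rep(charToRaw("N"), length(r) - length(g)))
    mm <- which(r != g)
    if (length(mm) && mm[1] <= 21L)
        stop("read 5' 21-mer does not match the reference")
    if (!length(mm)) {
        ## end-to-end match: no observable tail boundary; if the read ends
        ## in A the tail could have begun inside the match -> ambiguous
        if (substr(read, nchar(read), nchar(read)) == "A")
            return(NA_integer_)
        return(nchar(read))
    }
    k <- mm[1] - 1L  # matched prefix length
    tail <- rawToChar(r[mm[1]:length(r)])
    if (grepl("[^A]", tail))
        stop("read diverges from the reference with a non-poly-A tail")
    if (substr(read, k, k) == "A") return(NA_integer_)
    k
}

#' Place reads by exact 5' 21-mer match and size them
#'
#' Exact-prefix placement intended for synthetic libraries (genome-scale,
#' mismatch-tolerant alignment is delegated to external aligners, whose
#' output enters through \code{readFiveprimeTable}).  Each read's 5'
#' 21-mer is looked up in the dictionary of all 21-mers of the flanked ORF
#' sequences; reads with no unique placement are dropped and counted.
#' Placed reads are sized by the poly-A trimming rule.
#'
#' @param reads \code{DNAStringSet} or character vector of read sequences.
#' @param orfs an \code{OrfSet}.
#' @return Sized 5'-end table (orf_id, fiveprime, length with NA for
#'   ambiguous, count), with attribute "dropped" counting unplaced /
#'   multimapping / undeterminable reads.
#' @export
mapFiveprime <- function(reads, orfs) {
    reads <- as.character(reads)
    ids <- orfIds(orfs)
    pads <- Biostrings::width(orfs@upstream)
    dict_kmer <- character(0)
    dict_orf <- character(0)
    dict_pos <- integer(0)
    for (i in seq_along(ids)) {
        ext <- .extendedSeq(orfs, ids[i])
        npos <- nchar(ext) - 21L + 1L
        if (npos < 1L) next
        km <- substring(ext, seq_len(npos), seq_len(npos) + 20L)
        dict_kmer <- c(dict_kmer, km)
        dict_orf <- c(dict_orf, rep(ids[i], npos))
        dict_pos <- c(dict_pos, seq_len(npos) - 1L - pads[i])
    }
    multi <- unique(dict_kmer[duplicated(dict_kmer)])
    prefix <- substr(reads, 1L, 21L)
    hit <- match(prefix, dict_kmer)
    is_multi <- prefix %in% multi
    n_unplaced <- sum(is.na(hit) & !is_multi)
    n_multi <- sum(is_multi, na.rm = TRUE)
    use <- which(!is.na(hit) & !is_multi)
    orf <- dict_orf[hit[use]]
    fp <- dict_pos[hit[use]]
    len <- integer(length(use))
    n_undet <- 0L
    exts <- vapply(ids, function(id) .extendedSeq(orfs, id), character(1))
    for (j in seq_along(use)) {
        rd <- reads[use[j]]
        start <- fp[j] + pads[match(orf[j], ids)] + 1L
        ref <- substr(exts[[orf[j]]], start, start + nchar(rd) - 1L)
        len[j] <- tryCatch(.lengthFromComparison(rd, ref),
                           error = function(e) {
                               n_undet <<- n_undet + 1L
                               -1L
                           })
    }
    keep <- len != -1L | is.na(len)
    df <- data.frame(orf_id = orf[keep], fiveprime = fp[keep],
                     length = len[keep])
    key <- paste(df$orf_id, df$fiveprime, df$length, sep = "\r")
    tab <- rowsum(rep(1L, nrow(df)), key)
    first <- df[!duplicated(key), , drop = FALSE]
    first$count <- as.integer(tab[paste(first$orf_id, first$fiveprime,
                                        first$length, sep = "\r"), 1])
    out <- first[order(first$orf_id, first$fiveprime), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "dropped") <- c(unplaced = n_unplaced, multimapped = n_multi,
                              undetermined = n_undet)
    out
}

#' Read / write sized 5'-end tables
#'
#' Tab-delimited interchange format for pre-mapped reads: columns
#' \code{orf_id}, \code{fiveprime} (ORF-relative), \code{length}
#' (25-31 or "AMB" for ambiguous), \code{count}.
#'
#' @param path file path.
#' @param fp sized 5'-end table.
#' @return \code{readFiveprimeTable}: the table with ambiguous lengths as
#'   \code{NA}.
#' @export
readFiveprimeTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "integer",
                                           "character", "integer"))
    df$length <- suppressWarnings(as.integer(ifelse(df$length == "AMB",
                                                    NA, df$length)))
    df
}

#' @rdname readFiveprimeTable
#' @export
writeFiveprimeTable <- function(fp, path) {
    out <- fp[, c("orf_id", "fiveprime", "length", "count")]
    out$length <- ifelse(is.na(out$length), "AMB", as.character(out$length))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' The fixed reference P-site calibration
#'
#' The per-length offset/frame-shift table used when calibration is not
#' possible: offsets 12 nt for 25-28-mers, 13 nt for 29/30-mers, 14 nt for
#' 31-mers (frame shifts 0,0,0,0,-1,-1,-2 into the 28-mer frame).
#'
#' @return A \code{PsiteCalibration} with source "fixed-table".
#' @export
fixedCalibration <- function() {
    off <- as.numeric(.FIXED_OFFSETS)
    names(off) <- names(.FIXED_OFFSETS)
    new("PsiteCalibration", offsets = off,
        frame_shifts = off["28"] - off, source = "fixed-table",
        report = data.frame())
}

#' Calibrate P-site offsets from the start-codon metagene
#'
#' For each footprint length, pools 5' ends relative to the start codon
#' over a window and locates the modal upstream peak — reads whose P site
#' holds the start codon.  The peak distance d gives the P-site offset
#' (offset = -d) and the frame shift into the 28-mer frame
#' (shift = offset(28) - offset).  A length fails calibration when it has
#' fewer than \code{min_reads} in the window or its peak does not exceed
#' the mean off-peak background by \code{background_factor}; failed lengths
#' fall back to the fixed table only when \code{fallback_fixed} is set
#' (with a warning).
#'
#' @param fp sized 5'-end table (ambiguous lengths are ignored).
#' @param orfs an \code{OrfSet} (unused beyond interface symmetry; 5' ends
#'   are already ORF-relative).
#' @param min_reads minimum window reads per length (default 200).
#' @param background_factor required peak/background ratio (default 3).
#' @param window metagene window around position 0 (default c(-40, 20)).
#' @param fallback_fixed use the fixed table for failed lengths.
#' @return A \code{PsiteCalibration}.
#' @export
calibratePsite <- function(fp, orfs, min_reads = 200L,
                           background_factor = 3, window = c(-40L, 20L),
                           fallback_fixed = FALSE) {
    fp <- fp[!is.na(fp$length), , drop = FALSE]
    lens <- sort(unique(fp$length))
    positions <- seq(window[1], window[2])
    rows <- list()
    offsets <- stats::setNames(rep(NA_real_, length(lens)),
                               as.character(lens))
    for (L in lens) {
        sel <- fp$length == L & fp$fiveprime >= window[1] &
            fp$fiveprime <= window[2]
        meta <- stats::setNames(numeric(length(positions)),
                                positions)
        if (any(sel)) {
            sums <- rowsum(fp$count[sel], fp$fiveprime[sel])
            meta[rownames(sums)] <- sums[, 1]
        }
        n_win <- sum(meta)
        upstream <- meta[positions < 0]
        status <- "ok"
        peak_pos <- NA_integer_
        peak <- NA_real_
        bg <- NA_real_
        if (n_win < min_reads) {
            status <- "insufficient-reads"
        } else {
            mx <- max(upstream)
            cand <- as.integer(names(upstream)[upstream == mx])
            expected <- -(if (as.character(L) %in% names(.FIXED_OFFSETS))
                .FIXED_OFFSETS[[as.character(L)]] else 12L)
            peak_pos <- cand[which.min(abs(cand - expected))]
            peak <- mx
            bg <- mean(meta[names(meta) != as.character(peak_pos)])
            if (!(peak > background_factor * bg)) {
                status <- "no-peak"
                peak_pos <- NA_integer_
            } else {
                offsets[as.character(L)] <- -peak_pos
            }
        }
        rows[[as.character(L)]] <- data.frame(
            length = L, n_window = n_win, peak_pos = peak_pos,
            peak_count = peak, background = bg, status = status)
    }
    report <- do.call(rbind, rows)
    rownames(report) <- NULL
    source <- "calibrated"
    failed <- names(offsets)[is.na(offsets)]
    if (length(failed)) {
        if (fallback_fixed) {
            warning("falling back to the fixed offset table for length(s): ",
                    paste(failed, collapse = ", "))
            fb <- intersect(failed, names(.FIXED_OFFSETS))
            offsets[fb] <- .FIXED_OFFSETS[fb]
            source <- "fixed-table"
        } else {
            warning("calibration failed for length(s): ",
                    paste(failed, collapse = ", "))
        }
    }
    off28 <- if (!is.na(offsets["28"])) offsets[["28"]] else 12
    shifts <- off28 - offsets
    new("PsiteCalibration", offsets = offsets, frame_shifts = shifts,
        source = source, report = report)
}

#' Pool 5' ends and shift them into the 28-mer frame
#'
#' Builds the two track layers every downstream analysis consumes.  The
#' shifted layer pools length-split reads (25-31 nt, unambiguous) after
#' moving each record by its per-length frame shift (a negative shift
#' moves the 5' end 3'-ward), putting all lengths in frame with 28-mers.
#' The unsplit layer keeps every read, ambiguous lengths included, at its
#' raw 5' end.  Records outside the padded track or with uncalibrated /
#' out-of-range lengths are dropped from the shifted layer and counted.
#'
#' @param fp sized 5'-end table.
#' @param calibration a \code{PsiteCalibration}.
#' @param orfs an \code{OrfSet}.
#' @param pad_up,pad_down track padding in nt (defaults 60 / 30).
#' @return A \code{FootprintTracks}.
#' @examples
#' orfs <- buildSyntheticReference(n_orfs = 2, seed = 1)
#' fp <- data.frame(orf_id = orfIds(orfs)[1], fiveprime = -13L,
#'                  length = 29L, count = 1L)
#' tr <- poolAndFrameshift(fp, fixedCalibration(), orfs)
#' trackCount(tr, orfIds(orfs)[1], -12)  # 29-mer shifted 3'-ward by 1
#' @export
poolAndFrameshift <- function(fp, calibration, orfs, pad_up = 60L,
                              pad_down = 30L) {
    ids <- orfIds(orfs)
    nc <- nCodons(orfs)
    bad_orf <- setdiff(unique(fp$orf_id), ids)
    if (length(bad_orf))
        stop("5'-end table references unknown ORF(s): ",
             paste(bad_orf, collapse = ", "))
    tracklen <- pad_up + 3L * nc + pad_down
    newTracks <- function() {
        out <- lapply(tracklen, numeric)
        names(out) <- ids
        out
    }
    shifted <- newTracks()
    unsplit <- newTracks()
    dropped <- c(bad_length = 0, uncalibrated = 0, out_of_range = 0)
    ## unsplit layer: everything at its raw position
    idxu <- fp$fiveprime + pad_up + 1L
    oku <- idxu >= 1L & idxu <= tracklen[fp$orf_id]
    dropped["out_of_range"] <- sum(fp$count[!oku])
    ufp <- fp[oku, , drop = FALSE]
    for (id in unique(ufp$orf_id)) {
        s <- ufp[ufp$orf_id == id, ]
        sums <- rowsum(s$count, s$fiveprime + pad_up + 1L)
        unsplit[[id]][as.integer(rownames(sums))] <-
            unsplit[[id]][as.integer(rownames(sums))] + sums[, 1]
    }
    ## shifted layer: unambiguous 25-31-mers with a calibrated shift
    sfp <- fp[!is.na(fp$length), , drop = FALSE]
    inrange <- sfp$length >= 25L & sfp$length <= 31L
    if (any(!inrange)) {
        dropped["bad_length"] <- sum(sfp$count[!inrange])
        warning("dropping ", dropped["bad_length"],
                " read(s) with length outside 25-31 from the shifted pool")
        sfp <- sfp[inrange, , drop = FALSE]
    }
    sh <- frameShift(calibration, sfp$length)
    if (anyNA(sh)) {
        dropped["uncalibrated"] <- sum(sfp$count[is.na(sh)])
        sfp <- sfp[!is.na(sh), , drop = FALSE]
        sh <- sh[!is.na(sh)]
    }
    pos <- sfp$fiveprime - as.integer(sh)
    idx <- pos + pad_up + 1L
    ok <- idx >= 1L & idx <= tracklen[sfp$orf_id]
    dropped["out_of_range"] <- dropped["out_of_range"] + sum(sfp$count[!ok])
    sfp <- sfp[ok, , drop = FALSE]
    idx <- idx[ok]
    for (id in unique(sfp$orf_id)) {
        s <- sfp$orf_id == id
        sums <- rowsum(sfp$count[s], idx[s])
        shifted[[id]][as.integer(rownames(sums))] <-
            shifted[[id]][as.integer(rownames(sums))] + sums[, 1]
    }
    new("FootprintTracks", shifted = shifted, unsplit = unsplit,
        orf_ncodons = nc, pad_up = as.integer(pad_up),
        pad_down = as.integer(pad_down), dropped = dropped,
        totals = c(shifted = sum(unlist(shifted, use.names = FALSE)),
                   unsplit = sum(unlist(unsplit, use.names = FALSE))))
}

#' Pool replicate tracks
#'
#' Position-wise sum of counts across replicates, done before any
#' occupancy computation so the pooled statistic sees the combined reads.
#'
#' @param tracks_a,tracks_b \code{FootprintTracks} on the same reference.
#' @return The pooled \code{FootprintTracks}.
#' @export
poolReplicates <- function(tracks_a, tracks_b) {
    if (!identical(tracks_a@orf_ncodons, tracks_b@orf_ncodons) ||
        tracks_a@pad_up != tracks_b@pad_up ||
        tracks_a@pad_down != tracks_b@pad_down)
        stop("replicate tracks were built on different references")
    shifted <- Map(`+`, tracks_a@shifted, tracks_b@shifted)
    unsplit <- Map(`+`, tracks_a@unsplit, tracks_b@unsplit)
    new("FootprintTracks", shifted = shifted, unsplit = unsplit,
        orf_ncodons = tracks_a@orf_ncodons, pad_up = tracks_a@pad_up,
        pad_down = tracks_a@pad_down,
        dropped = tracks_a@dropped + tracks_b@dropped,
        totals = tracks_a@totals + tracks_b@totals)
}
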