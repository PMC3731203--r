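#' @include AllClasses.R accessors.R process.R
NULL

#' Gene-expression counting configuration
#'
#' The counting window runs from 12 nt upstream of the start codon to
#' 14 nt upstream of the stop codon, and the first 8 codons of each ORF
#' are excluded from all gene-expression calculations; the head exclusion
#' dominates the upstream pad, so the default window is
#' [3*8 - 12, L - 14) = [12, L - 14) where L is the position of the stop
#' codon's first nt.  Counting uses the unsplit 5'-end pool (every read at
#' its raw position, ambiguous lengths included).
#'
#' @param upstream_pad nt upstream of the start codon (default 12).
#' @param stop_pad nt upstream of the stop codon's first nt (default 14).
#' @param head_exclusion_codons excluded 5' codons (default 8).
#' @param use_unsplit_pool count on the unsplit layer (default TRUE).
#' @return A list of class "ExpressionConfig".
#' @export
expressionConfig <- function(upstream_pad = 12L, stop_pad = 14L,
                             head_exclusion_codons = 8L,
                             use_unsplit_pool = TRUE) {
    if (upstream_pad < 0L || stop_pad < 0L)
        stop("pads must be non-negative")
    structure(list(upstream_pad = as.integer(upstream_pad),
                   stop_pad = as.integer(stop_pad),
                   head_exclusion_codons = as.integer(head_exclusion_codons),
                   use_unsplit_pool = isTRUE(use_unsplit_pool)),
              class = "ExpressionConfig")
}

#' Count reads in an ORF's expression window
#'
#' Counts 5' ends in the half-open ORF-relative interval
#' [3*head_exclusion_codons - upstream_pad, L_stop - stop_pad), where
#' L_stop is the position of the stop codon's first nt.
#'
#' @param tracks a \code{FootprintTracks}.
#' @param orf_id ORF to count.
#' @param config an \code{expressionConfig}.
#' @return list(window_reads, window_length_nt, window_start, window_end,
#'   flagged); flagged is TRUE when the window is empty (tiny ORF).
#' @export
orfWindowCount <- function(tracks, orf_id, config = expressionConfig()) {
    ncod <- tracks@orf_ncodons[[orf_id]]
    L_stop <- 3L * (ncod - 1L)
    start <- 3L * config$head_exclusion_codons - config$upstream_pad
    end <- L_stop - config$stop_pad
    layer <- if (config$use_unsplit_pool) "unsplit" else "shifted"
    if (end <= start)
        return(list(window_reads = 0, window_length_nt = 0L,
                    window_start = start, window_end = end,
                    flagged = TRUE))
    reads <- sum(trackCount(tracks, orf_id, seq.int(start, end - 1L),
                            layer = layer))
    list(window_reads = reads, window_length_nt = end - start,
         window_start = start, window_end = end, flagged = FALSE)
}

#' RPKM expression table
#'
#' Reads per kilobase of ORF window per million ORF-assigned reads, where
#' the library size is the sum of window reads over all non-flagged ORFs.
#'
#' @param tracks a \code{FootprintTracks}.
#' @param orfs the matching \code{OrfSet}.
#' @param config an \code{expressionConfig}.
#' @param sample_id label stored on the table.
#' @return data.frame (orf_id, window_reads, window_length_nt, rpkm,
#'   flagged) with attributes "sample_id" and "library_orf_reads".
#' @export
rpkmTable <- function(tracks, orfs, config = expressionConfig(),
                      sample_id = NA_character_) {
    ids <- orfIds(orfs)
    rows <- lapply(ids, function(id) {
        wc <- orfWindowCount(tracks, id, config)
        data.frame(orf_id = id, window_reads = wc$window_reads,
                   window_length_nt = wc$window_length_nt,
                   flagged = wc$flagged)
    })
    out <- do.call(rbind, rows)
    lib <- sum(out$window_reads[!out$flagged])
    if (lib == 0) stop("zero ORF-assigned reads in the library")
    out$rpkm <- ifelse(out$flagged, NA_real_,
                       out$window_reads / (out$window_length_nt / 1000) /
                           (lib / 1e6))
    attr(out, "sample_id") <- sample_id
    attr(out, "library_orf_reads") <- lib
    out
}

#' Per-gene log2 fold changes with replicate means
#'
#' Pairs mutant and WT replicate expression tables positionally, computes
#' per-replicate log2 RPKM ratios, and returns their mean per gene.
#' Genes flagged or below \code{min_reads} window reads in any sample are
#' dropped and counted.
#'
#' @param records_mut,records_wt lists of \code{rpkmTable} outputs, one
#'   per replicate (a single table may be given directly).
#' @param min_reads minimum window reads in every sample (default 1).
#' @return data.frame (orf_id, log2_fc, n_replicates) with attribute
#'   "n_dropped".
#' @export
foldChangeTable <- function(records_mut, records_wt, min_reads = 1L) {
    asList <- function(x) if (is.data.frame(x)) list(x) else x
    records_mut <- asList(records_mut)
    records_wt <- asList(records_wt)
    if (length(records_mut) != length(records_wt))
        stop("replicate lists must have equal length")
    common <- Reduce(intersect, lapply(c(records_mut, records_wt),
                                       function(r) r$orf_id))
    if (!length(common)) stop("no genes shared across all samples")
    ok <- rep(TRUE, length(common))
    ratios <- matrix(NA_real_, length(common), length(records_mut))
    for (i in seq_along(records_mut)) {
        m <- records_mut[[i]][match(common, records_mut[[i]]$orf_id), ]
        w <- records_wt[[i]][match(common, records_wt[[i]]$orf_id), ]
        ok <- ok & !m$flagged & !w$flagged &
            m$window_reads >= min_reads & w$window_reads >= min_reads
        ratios[, i] <- log2(m$rpkm / w$rpkm)
    }
    out <- data.frame(orf_id = common[ok],
                      log2_fc = rowMeans(ratios[ok, , drop = FALSE]),
                      n_replicates = length(records_mut))
    if (!nrow(out)) stop("no genes pass the expression filter")
    attr(out, "n_dropped") <- sum(!ok)
    out
}

#' Hypergeometric gene-set overlap
#'
#' Upper-tail probability of observing at least the given overlap between
#' two gene sets drawn from a common background:
#' P(X >= overlap) with X ~ Hypergeometric(|A|, N - |A|, |B|).
#'
#' @param set_a,set_b character gene sets.
#' @param background character background universe containing both sets.
#' @return list (overlap_count, size_a, size_b, background_size,
#'   hypergeometric_p, overlap_genes).
#' @examples
#' hypergeometricOverlap(letters[1:5], letters[1:5], letters[1:10])
#' @export
hypergeometricOverlap <- function(set_a, set_b, background) {
    set_a <- unique(set_a)
    set_b <- unique(set_b)
    background <- unique(background)
    out_a <- setdiff(set_a, background)
    out_b <- setdiff(set_b, background)
    if (length(out_a) || length(out_b))
        stop("gene set members outside the background: ",
             paste(utils::head(c(out_a, out_b), 10L), collapse = ", "))
    ov <- intersect(set_a, set_b)
    p <- stats::phyper(length(ov) - 1L, length(set_a),
                       length(background) - length(set_a),
                       length(set_b), lower.tail = FALSE)
    list(overlap_count = length(ov), size_a = length(set_a),
         size_b = length(set_b), background_size = length(background),
         hypergeometric_p = p, overlap_genes = ov)
}

#' K-S enrichment of a target set's fold changes
#'
#' Two-sample K-S test of the target genes' fold changes against the rest
#' of the genome, with group medians (reported both as log2 and as fold).
#'
#' @param fold_changes data.frame with orf_id and log2_fc.
#' @param target_set character target gene ids.
#' @return list (ks_p, ks_D, n_target, n_rest, median_log2_target,
#'   median_log2_rest, median_fold_target, median_fold_rest).
#' @export
targetSetKs <- function(fold_changes, target_set) {
    is_t <- fold_changes$orf_id %in% target_set
    if (!any(is_t)) stop("no target gene has a fold change")
    if (all(is_t)) stop("target set leaves an empty complement")
    x <- fold_changes$log2_fc[is_t]
    y <- fold_changes$log2_fc[!is_t]
    kt <- suppressWarnings(stats::ks.test(x, y))
    list(ks_p = kt$p.value, ks_D = unname(kt$statistic),
         n_target = length(x), n_rest = length(y),
         median_log2_target = stats::median(x),
         median_log2_rest = stats::median(y),
         median_fold_target = 2^stats::median(x),
         median_fold_rest = 2^stats::median(y))
}

#' Correlation of footprint and transcript fold changes
#'
#' Pearson correlation over matched genes between Ribo-seq and RNA-seq
#' log2 fold changes.
#'
#' @param fc_ribo,fc_rna data.frames with orf_id and log2_fc.
#' @return list (r, n, table) where table holds the matched pairs.
#' @export
riboseqRnaseqCorrelation <- function(fc_ribo, fc_rna) {
    m <- merge(fc_ribo[, c("orf_id", "log2_fc")],
               fc_rna[, c("orf_id", "log2_fc")],
               by = "orf_id", suffixes = c("_ribo", "_rna"))
    if (nrow(m) < 3L)
        stop("need at least 3 matched genes, got ", nrow(m))
    list(r = stats::cor(m$log2_fc_ribo, m$log2_fc_rna), n = nrow(m),
         table = m)
}

#' Read a gene set file
#'
#' One gene id per line; blank lines and lines starting with '#' are
#' skipped.
#'
#' @param path file path.
#' @return character vector of ids.
#' @export
readGeneSet <- function(path) {
    x <- trimws(readLines(path, warn = FALSE))
    x[nzchar(x) & !startsWith(x, "#")]
}
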