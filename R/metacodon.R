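#' @include AllClasses.R accessors.R reference.R process.R
NULL

.META_SITE_MAP <- stats::setNames(
    as.integer(21L - .SITE_OFFSETS[c("-2", "-1", "A", "P", "E",
                                     "+1", "+2")]),
    c("-2", "-1", "A", "P", "E", "+1", "+2"))

## window sums around instances: raw[i+1] = sum over instances of
## track counts at (start_nt - back + i), i = 0..(width-1)
.windowSums <- function(tracks, instances, back, width) {
    raw <- numeric(width)
    if (!nrow(instances)) return(raw)
    for (id in unique(instances$orf_id)) {
        tr <- shiftedTrack(tracks, id)
        c0 <- instances$start_nt[instances$orf_id == id]
        base <- c0 - back + tracks@pad_up + 1L
        for (i in seq_len(width))
            raw[i] <- raw[i] + sum(tr[base + i - 1L])
    }
    raw
}

.normalizeOuter <- function(raw, outer_idx0, label) {
    om <- mean(raw[outer_idx0 + 1L])
    if (om == 0) {
        warning("zero outer-peak mean for ", label,
                "; normalized profile unavailable")
        return(rep(NA_real_, length(raw)))
    }
    raw / om
}

#' Compute a metacodon profile
#'
#' Aligns all in-frame instances of a codon and sums the pooled
#' frame-shifted 5'-end counts over the 21-nt window upstream of each
#' instance: \code{raw[i] = sum over instances at first-nt c of counts at
#' c - 21 + i}, i = 0..20.  The 21-nt offset is the 28-mer P-site offset
#' (12 nt) plus the 9-nt distance from the P site back to the window
#' start, so peaks at indices 0,3,6,9,12,15,18 place the codon in sites
#' -2,-1,A,P,E,+1,+2.  The normalized profile divides by the mean of the
#' four outer-site peaks (indices 0,3,15,18).  Instances within
#' \code{edge_exclusion_codons} of either ORF end are skipped so the whole
#' window lies in covered track space.
#'
#' @param codon a sense codon.
#' @param tracks a \code{FootprintTracks}.
#' @param orfs the matching \code{OrfSet}.
#' @param edge_exclusion_codons instance exclusion zone at ORF ends
#'   (default 7 codons).
#' @return A \code{MetacodonProfile}.
#' @export
computeMetacodon <- function(codon, tracks, orfs,
                             edge_exclusion_codons = 7L) {
    .checkCodon(codon)
    inst <- enumerateCodonInstances(orfs, codon)
    nc <- nCodons(orfs)
    keep <- inst$codon_index >= edge_exclusion_codons &
        inst$codon_index < nc[inst$orf_id] - edge_exclusion_codons
    inst <- inst[keep, , drop = FALSE]
    raw <- .windowSums(tracks, inst, back = 21L, width = 21L)
    outer <- unname(.META_SITE_MAP[c("-2", "-1", "+1", "+2")])
    normalized <- .normalizeOuter(raw, outer, paste0("codon ", codon))
    new("MetacodonProfile", codon = codon, raw = raw,
        normalized = normalized, n_instances = nrow(inst),
        site_map = .META_SITE_MAP, outer_sites = outer,
        window_offset = 21L)
}

#' Bulk codon occupancies from a metacodon profile
#'
#' The normalized peak heights at the seven in-frame window indices are
#' the bulk codon occupancies — a proxy for the relative time the
#' ribosome spends with the codon in each site.
#'
#' @param profile a \code{MetacodonProfile}.
#' @return Named numeric heights for sites -2,-1,A,P,E,+1,+2 (NA when
#'   normalization failed).
#' @export
bulkOccupancy <- function(profile) {
    stats::setNames(profile@normalized[profile@site_map + 1L],
                    names(profile@site_map))
}

#' Assemble the bulk occupancy table
#'
#' @param tracks a \code{FootprintTracks}.
#' @param orfs the matching \code{OrfSet}.
#' @param codons codons to profile (default all 61 sense codons).
#' @param sample_id label stored on the table.
#' @param edge_exclusion_codons passed to \code{computeMetacodon}.
#' @return data.frame (codon, site, height, raw_peak, n_instances) with
#'   attribute "sample_id".
#' @export
assembleBulkTable <- function(tracks, orfs, codons = .senseCodons(),
                              sample_id = NA_character_,
                              edge_exclusion_codons = 7L) {
    rows <- lapply(codons, function(cd) {
        pr <- suppressWarnings(
            computeMetacodon(cd, tracks, orfs, edge_exclusion_codons))
        h <- bulkOccupancy(pr)
        data.frame(codon = cd, site = names(h), height = as.numeric(h),
                   raw_peak = pr@raw[pr@site_map + 1L],
                   n_instances = pr@n_instances)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "sample_id") <- sample_id
    out
}

#' Bulk occupancy changes between samples
#'
#' Element-wise mutant/WT ratios of bulk occupancies from two identically
#' processed samples.
#'
#' @param mutant_table,wt_table tables from \code{assembleBulkTable}.
#' @return data.frame (codon, site, height_mut, height_wt, ratio,
#'   log2_ratio); zero or missing WT heights give NA ratios flagged in the
#'   \code{undefined} column.
#' @export
occupancyChange <- function(mutant_table, wt_table) {
    m <- merge(mutant_table[, c("codon", "site", "height")],
               wt_table[, c("codon", "site", "height")],
               by = c("codon", "site"), suffixes = c("_mut", "_wt"),
               all = TRUE)
    undefined <- is.na(m$height_wt) | is.na(m$height_mut) |
        m$height_wt == 0
    m$ratio <- ifelse(undefined, NA_real_, m$height_mut / m$height_wt)
    m$log2_ratio <- log2(m$ratio)
    m$undefined <- undefined
    m
}

#' Amino-acid-pair metaplot
#'
#' As \code{computeMetacodon}, but instances are the first codons of
#' adjacent codon pairs encoding a given amino-acid pair (standard genetic
#' code), and the window is extended 3 nt (24 positions) to cover both
#' codons.  With the window anchored at the first codon, index 9 is the
#' position where the first codon sits in the P site and the second in the
#' A site.  Outer-site normalization uses the first codon's -2/-1 peaks
#' (indices 0, 3) and the second codon's +1/+2 peaks (indices 18, 21).
#'
#' @param amino_acid_pair two one-letter amino-acid codes, e.g. "PG"
#'   (Pro then Gly) or \code{c("P","G")}.
#' @param tracks a \code{FootprintTracks}.
#' @param orfs the matching \code{OrfSet}.
#' @param edge_exclusion_codons instance exclusion zone (default 7).
#' @return A \code{MetacodonProfile} (codon slot holds the pair label);
#'   flagged empty (0 instances) when the pair never occurs.
#' @export
pairMetaplot <- function(amino_acid_pair, tracks, orfs,
                         edge_exclusion_codons = 7L) {
    aa <- if (length(amino_acid_pair) == 2L) amino_acid_pair
          else strsplit(amino_acid_pair, "")[[1]]
    code <- Biostrings::GENETIC_CODE
    if (length(aa) != 2L || !all(aa %in% setdiff(unique(code), "*")))
        stop("'amino_acid_pair' must be two standard amino-acid letters")
    ids <- orfIds(orfs)
    nc <- nCodons(orfs)
    inst <- lapply(ids, function(id) {
        cods <- .orfCodons(orfs, id)
        aas <- unname(code[cods])
        m <- which(aas[-length(aas)] == aa[1] & aas[-1] == aa[2]) - 1L
        m <- m[m >= edge_exclusion_codons &
               m < nc[[id]] - edge_exclusion_codons - 1L]
        if (!length(m)) return(NULL)
        data.frame(orf_id = id, codon_index = m, start_nt = 3L * m)
    })
    inst <- do.call(rbind, inst)
    if (is.null(inst))
        inst <- data.frame(orf_id = character(), codon_index = integer(),
                           start_nt = integer())
    if (!nrow(inst))
        warning("no instances of amino-acid pair ",
                paste(aa, collapse = "-"))
    raw <- .windowSums(tracks, inst, back = 21L, width = 24L)
    site_map <- c(.META_SITE_MAP, "+1'" = 21L)
    outer <- c(0L, 3L, 18L, 21L)
    normalized <- .normalizeOuter(raw, outer,
                                  paste0("pair ", paste(aa, collapse = "-")))
    new("MetacodonProfile", codon = paste(aa, collapse = "-"), raw = raw,
        normalized = normalized, n_instances = nrow(inst),
        site_map = site_map, outer_sites = outer, window_offset = 21L)
}

#' Correlate bulk occupancy with a per-codon metric
#'
#' Spearman rank correlation, per ribosomal site, between bulk codon
#' occupancies and an external per-codon metric such as the tRNA
#' adaptation index.
#'
#' @param bulk_table table from \code{assembleBulkTable}.
#' @param per_codon_metric named numeric metric over codons.
#' @param min_codons minimum codons with both values (default 50).
#' @return data.frame (site, rho, p_value, n); constant metrics give NA
#'   with a warning.
#' @export
correlateWithMetric <- function(bulk_table, per_codon_metric,
                                min_codons = 50L) {
    covered <- intersect(unique(bulk_table$codon),
                         names(per_codon_metric))
    if (length(covered) < min_codons)
        stop("metric covers only ", length(covered), " codons (need >= ",
             min_codons, ")")
    sites <- unique(bulk_table$site)
    rows <- lapply(sites, function(s) {
        sub <- bulk_table[bulk_table$site == s &
                          bulk_table$codon %in% covered, ]
        x <- sub$height
        y <- per_codon_metric[sub$codon]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3L || length(unique(y[ok])) == 1L) {
            warning("correlation undefined for site ", s)
            return(data.frame(site = s, rho = NA_real_,
                              p_value = NA_real_, n = sum(ok)))
        }
        ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                               method = "spearman"))
        data.frame(site = s, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(ok))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write bulk occupancy tables
#'
#' @param bulk table from \code{assembleBulkTable} or
#'   \code{occupancyChange}.
#' @param path output TSV.
#' @export
writeBulkTable <- function(bulk, path) {
    utils::write.table(bulk, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
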