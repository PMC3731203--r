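#' @include AllClasses.R accessors.R reference.R process.R
NULL

#' Single-codon occupancy configuration
#'
#' @param head_exclusion_codons codons excluded at the ORF 5' end
#'   (default 4).
#' @param min_inframe_reads minimum in-frame reads for a codon to enter
#'   both the record set and the density denominator (default 1; codons
#'   with no in-frame reads are excluded).
#' @param sites ribosomal sites to compute (default all seven).
#' @return A list of class "OccupancyConfig".
#' @export
occupancyConfig <- function(head_exclusion_codons = 4L,
                            min_inframe_reads = 1L,
                            sites = .SITE_NAMES) {
    if (head_exclusion_codons < 0L)
        stop("head_exclusion_codons must be non-negative")
    sites <- match.arg(sites, .SITE_NAMES, several.ok = TRUE)
    structure(list(head_exclusion_codons = as.integer(head_exclusion_codons),
                   min_inframe_reads = as.integer(min_inframe_reads),
                   sites = sites),
              class = "OccupancyConfig")
}

#' Single-codon occupancy
#'
#' For codon instance i of gene j in ribosomal site k, the occupancy is
#' the number of in-frame reads placing that codon in that site divided by
#' the gene's mean in-frame read density.  Only in-frame reads (5' ends a
#' multiple of 3 nt from the site's first nt, on the frame-shifted pooled
#' track) are counted; the first \code{head_exclusion_codons} codons and
#' codons with fewer than \code{min_inframe_reads} in-frame reads are
#' excluded from both the record set and the denominator, whose mean is
#' taken over the included codons only.
#'
#' @param tracks a \code{FootprintTracks}.
#' @param orfs the matching \code{OrfSet}.
#' @param sites sites to report (default "A").
#' @param config an \code{occupancyConfig}.
#' @return data.frame of records: orf_id, codon_index, codon, site,
#'   occupancy, numerator_reads, gene_mean_density.  Genes with no
#'   included codon contribute no records (counted in attribute
#'   "empty_genes").
#' @export
singleCodonOccupancy <- function(tracks, orfs, sites = "A",
                                 config = occupancyConfig()) {
    sites <- match.arg(sites, .SITE_NAMES, several.ok = TRUE)
    ids <- orfIds(orfs)
    nc <- nCodons(orfs)
    pad <- tracks@pad_up
    empty <- 0L
    out <- vector("list", length(ids) * length(sites))
    n <- 0L
    for (id in ids) {
        tr <- shiftedTrack(tracks, id)
        cods <- .orfCodons(orfs, id)
        m <- seq.int(0L, nc[[id]] - 1L)
        for (s in sites) {
            posidx <- 3L * m - .SITE_OFFSETS[[s]] + pad + 1L
            valid <- posidx >= 1L & posidx <= length(tr)
            cnt <- numeric(length(m))
            cnt[valid] <- tr[posidx[valid]]
            incl <- valid & m >= config$head_exclusion_codons &
                cnt >= config$min_inframe_reads
            if (!any(incl)) {
                empty <- empty + 1L
                next
            }
            dens <- sum(cnt[incl]) / sum(incl)
            n <- n + 1L
            out[[n]] <- data.frame(
                orf_id = id, codon_index = m[incl], codon = cods[incl],
                site = s, occupancy = cnt[incl] / dens,
                numerator_reads = cnt[incl], gene_mean_density = dens)
        }
    }
    if (empty > 0L)
        message(empty, " gene/site combination(s) had no included codons")
    res <- if (n) do.call(rbind, out[seq_len(n)])
           else data.frame(orf_id = character(), codon_index = integer(),
                           codon = character(), site = character(),
                           occupancy = numeric(),
                           numerator_reads = numeric(),
                           gene_mean_density = numeric())
    rownames(res) <- NULL
    attr(res, "empty_genes") <- empty
    res
}

#' Two-sample K-S comparison of occupancy distributions
#'
#' Compares the genome-wide distributions of single-codon occupancies for
#' one codon/site between two strains with the two-sided two-sample
#' Kolmogorov-Smirnov test.  The p-value is exact (full enumeration over
#' the label arrangements, ties handled) when the smaller sample has at
#' most 10 observations, asymptotic otherwise.
#'
#' @param occupancies_mut,occupancies_wt record tables from
#'   \code{singleCodonOccupancy}.
#' @param codon,site the codon/site cell to compare.
#' @return data.frame (codon, site, D_statistic, p_value, n1, n2).
#' @export
ksCompare <- function(occupancies_mut, occupancies_wt, codon, site) {
    x <- occupancies_mut$occupancy[occupancies_mut$codon == codon &
                                   occupancies_mut$site == site]
    y <- occupancies_wt$occupancy[occupancies_wt$codon == codon &
                                  occupancies_wt$site == site]
    if (!length(x) || !length(y))
        stop("empty occupancy sample for codon ", codon, " site ", site)
    .ksPair(x, y, codon, site)
}

.ksPair <- function(x, y, codon, site) {
    exact <- min(length(x), length(y)) <= 10L
    kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
    data.frame(codon = codon, site = site,
               D_statistic = unname(kt$statistic),
               p_value = kt$p.value, n1 = length(x), n2 = length(y))
}

#' K-S p-value grid over codons and sites
#'
#' @param occupancies_mut,occupancies_wt record tables covering the
#'   requested codons/sites.
#' @param codons rows of the grid (default all 61 sense codons).
#' @param sites columns (default all seven sites).
#' @return list with matrices \code{p}, \code{log10_p} and \code{D}
#'   (codons x sites); cells with an empty sample are NA.  p-values are
#'   reported raw (no multiple-testing adjustment), matching the heatmap
#'   display convention.
#' @export
ksHeatmap <- function(occupancies_mut, occupancies_wt,
                      codons = .senseCodons(), sites = .SITE_NAMES) {
    splitOcc <- function(df) split(df$occupancy,
                                   list(codon = df$codon, site = df$site),
                                   drop = TRUE)
    gm <- splitOcc(occupancies_mut)
    gw <- splitOcc(occupancies_wt)
    p <- D <- matrix(NA_real_, length(codons), length(sites),
                     dimnames = list(codons, sites))
    for (cd in codons) for (s in sites) {
        key <- paste(cd, s, sep = ".")
        x <- gm[[key]]
        y <- gw[[key]]
        if (is.null(x) || is.null(y)) next
        r <- .ksPair(x, y, cd, s)
        p[cd, s] <- r$p_value
        D[cd, s] <- r$D_statistic
    }
    list(p = p, log10_p = log10(p), D = D)
}

#' Per-instance fold changes versus read coverage
#'
#' Matches codon instances between conditions by (orf_id, codon_index,
#' site), computes occupancy fold changes (mutant/WT), and bins them by
#' WT numerator read coverage on a log2 scale to expose the
#' coverage-dependence of the metric.
#'
#' @param occ_mut,occ_wt record tables from \code{singleCodonOccupancy}.
#' @param codon_sets named list of codon vectors defining the summary
#'   groups (e.g. \code{list(VAA = c("AAA","CAA","GAA"))}); instances in
#'   no set are pooled as "Other".
#' @param bin_width_log2 coverage bin width (default 0.2).
#' @param min_reads read threshold for the confident-change summary
#'   (default 32).
#' @param min_reads_mode "each" requires \code{min_reads} in both
#'   conditions; "combined" requires it of their sum.
#' @return list: \code{instances} (matched table with fold_change,
#'   log2_coverage, set, passes_min_reads), \code{binned} (per set x bin
#'   mean fold change and n), \code{max_fold_confident} (largest fold
#'   change among instances passing the read threshold).  The threshold
#'   mode is recorded in attribute "min_reads_mode".
#' @export
foldChangeVsCoverage <- function(occ_mut, occ_wt,
                                 codon_sets = list(),
                                 bin_width_log2 = 0.2,
                                 min_reads = 32L,
                                 min_reads_mode = c("each", "combined")) {
    min_reads_mode <- match.arg(min_reads_mode)
    m <- merge(occ_mut, occ_wt,
               by = c("orf_id", "codon_index", "codon", "site"),
               suffixes = c("_mut", "_wt"))
    if (!nrow(m)) {
        warning("no matched codon instances between conditions")
        return(structure(list(instances = m, binned = NULL,
                              max_fold_confident = NA_real_),
                         min_reads_mode = min_reads_mode))
    }
    m$fold_change <- m$occupancy_mut / m$occupancy_wt
    m$log2_coverage <- log2(m$numerator_reads_wt)
    m$set <- "Other"
    for (nm in names(codon_sets))
        m$set[m$codon %in% codon_sets[[nm]]] <- nm
    m$passes_min_reads <- if (min_reads_mode == "each")
        m$numerator_reads_mut >= min_reads &
            m$numerator_reads_wt >= min_reads
    else m$numerator_reads_mut + m$numerator_reads_wt >= min_reads
    m$bin <- floor(m$log2_coverage / bin_width_log2) * bin_width_log2
    agg <- stats::aggregate(fold_change ~ set + bin, data = m, FUN = mean)
    agg$n <- stats::aggregate(fold_change ~ set + bin, data = m,
                              FUN = length)$fold_change
    colnames(agg)[colnames(agg) == "fold_change"] <- "mean_fold_change"
    maxf <- if (any(m$passes_min_reads))
        max(m$fold_change[m$passes_min_reads]) else NA_real_
    structure(list(instances = m, binned = agg,
                   max_fold_confident = maxf),
              min_reads_mode = min_reads_mode)
}

#' Mean inter-ribosome spacing in codons
#'
#' Converts a mean ribosome density (one ribosome per so many nt) into the
#' mean spacing in codons — the elongation-delay budget a single slow
#' codon would have to exceed before elongation, rather than initiation,
#' became rate-limiting for a transcript of average density.
#'
#' @param nt_per_ribosome mean nt of mRNA per ribosome (default 164).
#' @return Spacing in codons.
#' @export
interRibosomeSpacing <- function(nt_per_ribosome = 164) {
    nt_per_ribosome / 3
}

#' Write occupancy records
#'
#' @param occ record table.
#' @param path output TSV.
#' @export
writeOccupancyTable <- function(occ, path) {
    utils::write.table(occ, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
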