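#' @include AllClasses.R accessors.R reference.R
NULL

#' Build a synthetic ORF reference
#'
#' Generates a reproducible set of ORFs with controllable codon usage and
#' flank base composition.  Each ORF starts with ATG, ends with a stop
#' codon sampled from TAA/TAG/TGA, and carries random flanks whose base
#' composition is \code{flank_composition} — setting its A weight to zero
#' forces every footprint that ends at an ORF/flank boundary to be
#' unambiguous under the poly-A trimming rule.
#'
#' @param n_orfs number of ORFs.
#' @param length_range_codons inclusive range of total codons (start and
#'   stop included); minimum 20.
#' @param codon_usage_weights named positive weights over the 61 sense
#'   codons (default uniform); codons absent from the names get weight 0.
#' @param flank_composition named weights over A, C, G, T.
#' @param flank_nt flank width (default 60).
#' @param seed integer seed; the same seed gives byte-identical output.
#' @return An \code{OrfSet}.
#' @export
buildSyntheticReference <- function(n_orfs = 20L,
                                    length_range_codons = c(150L, 300L),
                                    codon_usage_weights = NULL,
                                    flank_composition = c(A = 1, C = 1,
                                                          G = 1, T = 1),
                                    flank_nt = 60L, seed = 1L) {
    sense <- .senseCodons()
    if (is.null(codon_usage_weights)) {
        w <- stats::setNames(rep(1, length(sense)), sense)
    } else {
        w <- stats::setNames(numeric(length(sense)), sense)
        w[names(codon_usage_weights)] <- codon_usage_weights
    }
    if (any(w < 0) || sum(w) == 0)
        stop("codon usage weights must be non-negative with positive sum")
    if (min(length_range_codons) < 20L)
        stop("ORFs must be at least 20 codons long")
    fc <- flank_composition[c("A", "C", "G", "T")]
    fc[is.na(fc)] <- 0
    if (sum(fc) == 0) stop("flank composition must have positive sum")
    set.seed(seed)
    ids <- sprintf("ORF%04d", seq_len(n_orfs))
    ncod <- sample(seq(length_range_codons[1], length_range_codons[2]),
                   n_orfs, replace = TRUE)
    sampleFlank <- function()
        paste(sample(c("A", "C", "G", "T"), flank_nt, replace = TRUE,
                     prob = fc), collapse = "")
    coding <- vapply(ncod, function(nc) {
        body <- sample(sense, nc - 2L, replace = TRUE, prob = w)
        paste0("ATG", paste(body, collapse = ""),
               sample(.STOP_CODONS, 1L))
    }, character(1))
    names(coding) <- ids
    up <- vapply(ids, function(i) sampleFlank(), character(1))
    down <- vapply(ids, function(i) sampleFlank(), character(1))
    OrfSet(coding, upstream = up, downstream = down)
}

#' Construct simulation ground truth
#'
#' All arguments default to the standard study conditions: footprint
#' lengths 25-31 nt centred on 28-mers, the fixed per-length P-site offset
#' table (25-28: 12 nt, 29/30: 13 nt, 31: 14 nt), geometric poly-A tails of
#' at least 4 nt, no queuing, and a 5\% start-codon initiation peak.
#'
#' @param orfs the \code{OrfSet} the truth refers to.
#' @param gene_flux named positive weights (default: equal flux).
#' @param length_probs named probabilities over footprint lengths; default
#'   peaks at 28 nt.
#' @param psite_offset named length -> offset map (default fixed table).
#' @param tail_lengths,tail_probs poly-A tail distribution.
#' @param queue_probability,init_peak_prob,seed see class docs.
#' @return A \code{SimulationTruth}.
#' @export
simulationTruth <- function(orfs, gene_flux = NULL,
                            length_probs = c("25" = 0.05, "26" = 0.10,
                                             "27" = 0.15, "28" = 0.40,
                                             "29" = 0.15, "30" = 0.10,
                                             "31" = 0.05),
                            psite_offset = .FIXED_OFFSETS,
                            tail_lengths = 4:20,
                            tail_probs = stats::dgeom(0:16, 0.25),
                            queue_probability = 0,
                            init_peak_prob = 0.05, seed = 1L) {
    ids <- orfIds(orfs)
    if (is.null(gene_flux))
        gene_flux <- stats::setNames(rep(1, length(ids)), ids)
    if (!all(ids %in% names(gene_flux)))
        stop("gene_flux must cover every ORF")
    gene_flux <- gene_flux[ids]
    dwell <- matrix(1, nrow = length(.SITE_NAMES),
                    ncol = length(.allCodons()),
                    dimnames = list(.SITE_NAMES, .allCodons()))
    new("SimulationTruth", gene_flux = gene_flux, dwell = dwell,
        length_probs = length_probs / sum(length_probs),
        psite_offset = psite_offset,
        tail_lengths = as.integer(tail_lengths),
        tail_probs = tail_probs / sum(tail_probs),
        queue_probability = queue_probability,
        init_peak_prob = init_peak_prob, seed = as.integer(seed))
}

#' Set a dwell-time multiplier
#'
#' @param truth a \code{SimulationTruth}.
#' @param site ribosomal site, one of -2, -1, E, P, A, +1, +2.
#' @param codon codon(s) whose dwell at that site is scaled.
#' @param value positive multiplier.
#' @return The modified truth.
#' @export
setDwell <- function(truth, site, codon, value) {
    site <- match.arg(site, .SITE_NAMES)
    for (cd in codon) .checkCodon(cd)
    if (value <= 0) stop("dwell multipliers must be positive")
    truth@dwell[site, codon] <- value
    validObject(truth)
    truth
}

## fast grouped count aggregation for large read draws
.aggregateCounts <- function(df) {
    key <- do.call(paste, c(unname(df), list(sep = "\r")))
    tab <- rowsum(rep(1L, nrow(df)), key)
    parts <- strsplit(rownames(tab), "\r", fixed = TRUE)
    out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    colnames(out) <- colnames(df)
    for (cl in colnames(df))
        if (is.numeric(df[[cl]])) out[[cl]] <- as.integer(out[[cl]])
    out$count <- as.integer(tab[, 1])
    out
}

## per-ORF table of eligible P-site codon indices and their sampling
## weights under the multiplicative 7-site dwell model; stall_sites adds
## instance-level A-site multipliers on top of the codon-level dwell model
.positionWeights <- function(orfs, truth, stall_sites = NULL) {
    ids <- orfIds(orfs)
    nc <- nCodons(orfs)
    short <- ids[nc < 8L]
    if (length(short)) {
        warning("skipping ORF(s) shorter than the 7-codon context window: ",
                paste(short, collapse = ", "))
        ids <- setdiff(ids, short)
    }
    tabs <- lapply(ids, function(id) {
        n <- nc[[id]]
        k <- seq.int(3L, n - 4L)
        cods <- .orfCodons(orfs, id)
        w <- rep(truth@gene_flux[[id]], length(k))
        for (s in .SITE_NAMES) {
            idx <- k + .SITE_DELTAS[[s]]
            w <- w * truth@dwell[s, cods[idx + 1L]]
        }
        data.frame(orf_id = id, psite_index = k, weight = w)
    })
    pw <- do.call(rbind, tabs)
    if (!is.null(stall_sites) && nrow(stall_sites)) {
        bad <- setdiff(unique(stall_sites$orf_id), ids)
        if (length(bad))
            stop("stall site(s) in unknown ORF(s): ",
                 paste(bad, collapse = ", "))
        mult <- if ("multiplier" %in% colnames(stall_sites))
            stall_sites$multiplier else rep(3, nrow(stall_sites))
        ## the stalled codon occupies the A site when the P site is one
        ## codon upstream
        key <- paste(pw$orf_id, pw$psite_index + 1L)
        hit <- match(key, paste(stall_sites$orf_id,
                                stall_sites$codon_index))
        pw$weight[!is.na(hit)] <- pw$weight[!is.na(hit)] *
            mult[hit[!is.na(hit)]]
    }
    pw
}

#' Simulate a ribosome footprint library
#'
#' Draws P-site codon positions with probability proportional to gene flux
#' times the product of the seven site-specific dwell multipliers of the
#' codons occupying the -2..+2 sites (positions whose 7-codon context
#' extends outside the ORF are excluded from bulk sampling).  A fraction
#' \code{init_peak_prob} of reads is instead placed with the start codon in
#' the P site.  Each read's length is drawn from the length distribution
#' and its 5' end is the P-site position minus the per-length offset
#' (no digestion jitter unless \code{jitter_nt} is set).
#'
#' @param orfs an \code{OrfSet}.
#' @param truth a \code{SimulationTruth}.
#' @param n_reads number of footprints.
#' @param seed integer seed (defaults to the truth's seed).
#' @param jitter_nt if \code{TRUE}, perturb each 5' end by -1/0/+1 nt with
#'   probabilities 0.15/0.7/0.15 (robustness checks only; default off).
#' @param stall_sites optional data.frame (orf_id, codon_index, optional
#'   multiplier, default 3) of individual codon instances whose A-site
#'   dwell is scaled on top of the codon-level model — the generative
#'   counterpart of site-specific stalls used in queuing studies.
#' @return data.frame of aggregated reads: orf_id, psite_index (codon index
#'   of the P-site codon), length, fiveprime (ORF-relative 5'-end
#'   position), count.  The truth is attached as attribute "truth".
#' @export
simulateFootprints <- function(orfs, truth, n_reads, seed = NULL,
                               jitter_nt = FALSE, stall_sites = NULL) {
    if (n_reads < 1L) stop("n_reads must be at least 1")
    if (is.null(seed)) seed <- truth@seed
    set.seed(seed)
    pw <- .positionWeights(orfs, truth, stall_sites)
    if (!nrow(pw)) stop("no ORF long enough to simulate")
    n_init <- stats::rbinom(1L, n_reads, truth@init_peak_prob)
    n_bulk <- n_reads - n_init
    pick <- sample.int(nrow(pw), n_bulk, replace = TRUE, prob = pw$weight)
    orf <- pw$orf_id[pick]
    k <- pw$psite_index[pick]
    if (n_init > 0L) {
        ids <- unique(pw$orf_id)
        flux <- truth@gene_flux[ids]
        iorf <- sample(ids, n_init, replace = TRUE, prob = flux)
        orf <- c(orf, iorf)
        k <- c(k, rep(0L, n_init))
    }
    lens <- as.integer(sample(names(truth@length_probs), length(orf),
                              replace = TRUE, prob = truth@length_probs))
    fp <- 3L * k - as.integer(truth@psite_offset[as.character(lens)])
    if (isTRUE(jitter_nt))
        fp <- fp + sample(c(-1L, 0L, 1L), length(fp), replace = TRUE,
                          prob = c(0.15, 0.7, 0.15))
    agg <- .aggregateCounts(data.frame(orf_id = orf, psite_index = k,
                                       length = lens, fiveprime = fp,
                                       stringsAsFactors = FALSE))
    agg <- agg[order(agg$orf_id, agg$fiveprime, agg$length), ]
    rownames(agg) <- NULL
    attr(agg, "truth") <- truth
    agg
}

#' Materialize read sequences for simulated footprints
#'
#' Expands an aggregated read table into per-read sequences: the reference
#' slice at (fiveprime, fiveprime + length) plus a sampled poly-A tail.
#'
#' @param orfs an \code{OrfSet} (flanks must cover the 5' ends).
#' @param reads table from \code{simulateFootprints}/\code{injectQueue}.
#' @param truth a \code{SimulationTruth} (tail model).
#' @param seed integer seed for tail lengths.
#' @return A \code{DNAStringSet}; names encode read id, ORF, position and
#'   true length.
#' @export
makeReadSequences <- function(orfs, reads, truth, seed = 1L) {
    set.seed(seed)
    idx <- rep(seq_len(nrow(reads)), reads$count)
    orf <- reads$orf_id[idx]
    fp <- reads$fiveprime[idx]
    len <- reads$length[idx]
    tails <- sample(truth@tail_lengths, length(idx), replace = TRUE,
                    prob = truth@tail_probs)
    ids <- orfIds(orfs)
    ext <- vapply(ids, function(id) .extendedSeq(orfs, id), character(1))
    pad <- Biostrings::width(orfs@upstream)
    names(pad) <- ids
    start <- fp + pad[orf] + 1L
    body <- substr(ext[orf], start, start + len - 1L)
    if (any(nchar(body) != len))
        stop("read extends beyond the available flank sequence")
    seqs <- Biostrings::DNAStringSet(paste0(body, strrep("A", tails)))
    names(seqs) <- sprintf("read%07d|%s|%d|%d", seq_along(idx), orf, fp, len)
    seqs
}

#' Write reads as FASTQ
#'
#' @param seqs a \code{DNAStringSet} of read sequences.
#' @param path output FASTQ path.
#' @export
writeFootprintFastq <- function(seqs, path) {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = quals)
    invisible(path)
}

#' Inject stacked trailing ribosomes behind stall sites
#'
#' For each simulated read whose A-site codon is a designated stall codon,
#' emits (with the truth's queue probability) an extra read whose 5' end
#' lies \code{spacing_nt} upstream (5'-end to 5'-end distance), with the
#' same length.
#'
#' @param reads table from \code{simulateFootprints}.
#' @param truth a \code{SimulationTruth} (supplies queue_probability).
#' @param stall_positions data.frame with orf_id and codon_index of the
#'   stalled (A-site) codons.
#' @param spacing_nt 5'-to-5' spacing of the trailing read (default 28).
#' @param seed integer seed.
#' @param mode "sampled" draws binomial trailing counts; "expected" emits
#'   the rounded expected count deterministically.
#' @return The augmented read table; injected rows carry queued = TRUE.
#' @export
injectQueue <- function(reads, truth, stall_positions, spacing_nt = 28L,
                        seed = 1L, mode = c("sampled", "expected")) {
    mode <- match.arg(mode)
    if (!all(c("orf_id", "codon_index") %in% colnames(stall_positions)))
        stop("stall_positions needs orf_id and codon_index columns")
    known <- unique(reads$orf_id)
    bad <- setdiff(unique(stall_positions$orf_id), known)
    if (length(bad))
        stop("stall position(s) in ORF(s) absent from the library: ",
             paste(bad, collapse = ", "))
    reads$queued <- FALSE
    key <- paste(stall_positions$orf_id, stall_positions$codon_index)
    lead <- paste(reads$orf_id, reads$psite_index + 1L) %in% key
    if (!any(lead) || truth@queue_probability == 0) return(reads)
    set.seed(seed)
    src <- reads[lead, , drop = FALSE]
    extra <- if (mode == "sampled")
        stats::rbinom(nrow(src), src$count, truth@queue_probability)
    else as.integer(round(src$count * truth@queue_probability))
    keep <- extra > 0L
    if (!any(keep)) return(reads)
    q <- src[keep, , drop = FALSE]
    q$count <- extra[keep]
    q$fiveprime <- q$fiveprime - as.integer(spacing_nt)
    q$psite_index <- NA_integer_
    q$queued <- TRUE
    out <- rbind(reads, q)
    rownames(out) <- NULL
    attr(out, "truth") <- attr(reads, "truth")
    out
}

#' Simulate a matched RNA-seq library
#'
#' Read 5' ends are uniform over each transcript's coding sequence, with
#' per-gene read mass proportional to abundance times the number of valid
#' start positions.
#'
#' @param orfs an \code{OrfSet}.
#' @param abundances named non-negative transcript abundances.
#' @param n_reads total reads.
#' @param read_length read length in nt.
#' @param seed integer seed.
#' @return Aggregated read table (orf_id, fiveprime, length, count).
#' @export
simulateRnaseq <- function(orfs, abundances, n_reads, read_length = 36L,
                           seed = 1L) {
    if (length(abundances) == 0L) stop("abundance table is empty")
    ids <- intersect(orfIds(orfs), names(abundances))
    if (!length(ids)) stop("no abundance entry matches the reference")
    nc <- nCodons(orfs)[ids]
    npos <- pmax(3L * nc - as.integer(read_length) + 1L, 0L)
    w <- abundances[ids] * npos
    if (sum(w) == 0) stop("all transcript weights are zero")
    set.seed(seed)
    orf <- sample(ids, n_reads, replace = TRUE, prob = w)
    fp <- as.integer(floor(stats::runif(n_reads) * npos[orf]))
    agg <- .aggregateCounts(data.frame(orf_id = orf, fiveprime = fp,
                                       stringsAsFactors = FALSE))
    agg$length <- as.integer(read_length)
    agg <- agg[order(agg$orf_id, agg$fiveprime),
               c("orf_id", "fiveprime", "length", "count")]
    rownames(agg) <- NULL
    agg
}

#' Write simulation truth tables
#'
#' Emits plain TSVs of the generative parameters: gene fluxes, non-unit
#' dwell multipliers, the length distribution with per-length P-site
#' offsets, and the scalar settings.
#'
#' @param truth a \code{SimulationTruth}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeTruthTables <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(dir, "gene_flux.tsv")
    utils::write.table(data.frame(orf_id = names(truth@gene_flux),
                                  flux = truth@gene_flux),
                       p1, sep = "\t", quote = FALSE, row.names = FALSE)
    nz <- which(truth@dwell != 1, arr.ind = TRUE)
    dm <- data.frame(site = rownames(truth@dwell)[nz[, 1]],
                     codon = colnames(truth@dwell)[nz[, 2]],
                     multiplier = truth@dwell[nz])
    p2 <- file.path(dir, "dwell_multipliers.tsv")
    utils::write.table(dm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    p3 <- file.path(dir, "length_model.tsv")
    utils::write.table(data.frame(length = names(truth@length_probs),
                                  prob = truth@length_probs,
                                  psite_offset = truth@psite_offset[
                                      names(truth@length_probs)]),
                       p3, sep = "\t", quote = FALSE, row.names = FALSE)
    p4 <- file.path(dir, "settings.tsv")
    utils::write.table(data.frame(
        key = c("queue_probability", "init_peak_prob", "seed"),
        value = c(truth@queue_probability, truth@init_peak_prob,
                  truth@seed)),
        p4, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(p1, p2, p3, p4))
}
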