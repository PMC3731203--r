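#' @include AllClasses.R accessors.R
NULL

#' Read an ORF annotation table
#'
#' Reads the minimal 6-column tab-delimited dialect used throughout the
#' package: \code{orf_id}, \code{chrom}, \code{strand} (+/-),
#' \code{block_starts}, \code{block_ends} (comma-joined 0-based half-open
#' genomic coordinates of the coding exon blocks, ordered 5' to 3' on the
#' genome), \code{frame} (ignored; 0 assumed).  A BED12 reader is available
#' through \code{format = "bed12"} (requires \pkg{rtracklayer}); thick
#' coordinates are ignored and the full blocks are taken as coding.
#'
#' @param path annotation file.
#' @param format "tsv" (default) or "bed12".
#' @return data.frame with columns orf_id, chrom, strand, block_starts,
#'   block_ends (the last two as lists of integer vectors).
#' @export
readOrfAnnotation <- function(path, format = c("tsv", "bed12")) {
    format <- match.arg(format)
    if (format == "bed12") {
        if (!requireNamespace("rtracklayer", quietly = TRUE))
            stop("BED12 input requires the rtracklayer package")
        gr <- rtracklayer::import(path, format = "bed")
        blocks <- rtracklayer::blocks(gr)
        starts <- lapply(seq_along(blocks), function(i)
            BiocGenerics::start(blocks[[i]]) - 1L)
        ends <- lapply(seq_along(blocks), function(i)
            BiocGenerics::end(blocks[[i]]))
        return(data.frame(orf_id = gr$name,
                          chrom = as.character(GenomicRanges::seqnames(gr)),
                          strand = as.character(BiocGenerics::strand(gr)),
                          block_starts = I(starts), block_ends = I(ends)))
    }
    ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character")
    need <- c("orf_id", "chrom", "strand", "block_starts", "block_ends")
    if (!all(need %in% colnames(ann)))
        stop("annotation must contain columns: ",
             paste(need, collapse = ", "))
    splitInts <- function(x) lapply(strsplit(x, ","), as.integer)
    data.frame(orf_id = ann$orf_id, chrom = ann$chrom,
               strand = ann$strand,
               block_starts = I(splitInts(ann$block_starts)),
               block_ends = I(splitInts(ann$block_ends)))
}

#' Load a reference genome and ORF annotation
#'
#' Splices each ORF's coding sequence from the genome (reverse-complementing
#' minus-strand genes), attaches up/downstream flanks on the coding strand
#' clipped at contig ends, and returns the set in the ORF-relative frame
#' (position 0 = first nt of the start codon).  ORFs whose coding sequence
#' violates the multiple-of-3 / start / stop invariants are flagged with a
#' warning but retained.
#'
#' @param fasta_path genome FASTA.
#' @param annotation_path annotation file (see \code{readOrfAnnotation}).
#' @param format annotation dialect.
#' @param flank_nt flank width to extract (default 60).
#' @return An \code{OrfSet} ordered by ORF id.
#' @export
loadReference <- function(fasta_path, annotation_path,
                          format = c("tsv", "bed12"), flank_nt = 60L) {
    genome <- Biostrings::readDNAStringSet(fasta_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    ann <- readOrfAnnotation(annotation_path, format = match.arg(format))
    missing <- setdiff(unique(ann$chrom), names(genome))
    if (length(missing))
        stop("annotation references sequence id(s) absent from the FASTA: ",
             paste(missing, collapse = ", "))
    gchar <- as.character(genome)
    glen <- nchar(gchar)
    names(glen) <- names(genome)
    n <- nrow(ann)
    coding <- character(n)
    up <- character(n)
    down <- character(n)
    pl_starts <- character(n)
    pl_ends <- character(n)
    for (i in seq_len(n)) {
        s <- ann$block_starts[[i]]
        e <- ann$block_ends[[i]]
        if (length(s) != length(e) || any(e <= s))
            stop("malformed blocks for ORF '", ann$orf_id[i], "'")
        if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)]))
            stop("exon blocks must be ordered and non-overlapping for ORF '",
                 ann$orf_id[i], "'")
        chrom <- ann$chrom[i]
        gseq <- gchar[[chrom]]
        pieces <- substring(gseq, s + 1L, e)
        spliced <- paste(pieces, collapse = "")
        lo <- max(0L, s[1] - flank_nt)
        left <- substring(gseq, lo + 1L, s[1])
        hi <- min(glen[[chrom]], e[length(e)] + flank_nt)
        right <- substring(gseq, e[length(e)] + 1L, hi)
        if (ann$strand[i] == "-") {
            rc <- function(x) as.character(
                Biostrings::reverseComplement(Biostrings::DNAString(x)))
            coding[i] <- rc(spliced)
            up[i] <- rc(right)
            down[i] <- rc(left)
        } else {
            coding[i] <- spliced
            up[i] <- left
            down[i] <- right
        }
        pl_starts[i] <- paste(s, collapse = ",")
        pl_ends[i] <- paste(e, collapse = ",")
    }
    names(coding) <- ann$orf_id
    placement <- S4Vectors::DataFrame(chrom = ann$chrom,
                                      strand = ann$strand,
                                      block_starts = pl_starts,
                                      block_ends = pl_ends)
    OrfSet(coding, upstream = up, downstream = down, placement = placement)
}

#' Write an OrfSet as FASTA plus annotation
#'
#' Emits a one-contig-per-ORF layout (contig = upstream flank + coding +
#' downstream flank, plus strand) with a matching 6-column annotation, so
#' that \code{loadReference} on the pair round-trips coding sequences and
#' coordinates exactly (for flanks up to \code{flank_nt}).
#'
#' @param orfs an \code{OrfSet}.
#' @param fasta_path,annotation_path output paths.
#' @return Invisibly, the annotation data.frame written.
#' @export
writeReference <- function(orfs, fasta_path, annotation_path) {
    ids <- orfIds(orfs)
    upw <- Biostrings::width(orfs@upstream)
    cw <- Biostrings::width(orfs@coding)
    contigs <- Biostrings::DNAStringSet(vapply(ids, function(id)
        .extendedSeq(orfs, id), character(1)))
    names(contigs) <- paste0("contig_", ids)
    Biostrings::writeXStringSet(contigs, fasta_path)
    ann <- data.frame(orf_id = ids, chrom = paste0("contig_", ids),
                      strand = "+", block_starts = upw,
                      block_ends = upw + cw, frame = 0L)
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(ann)
}

#' Enumerate in-frame instances of a codon
#'
#' Returns every in-frame occurrence (codon-aligned reading positions only;
#' out-of-frame matches are not instances) of \code{codon} across the coding
#' sequences.
#'
#' @param orfs an \code{OrfSet}.
#' @param codon a 3-mer over ACGT.
#' @return data.frame with orf_id, codon_index (0-based), codon and
#'   start_nt (= 3 * codon_index).
#' @examples
#' orfs <- OrfSet(c(g = "ATGAAAAAATAA"))
#' enumerateCodonInstances(orfs, "AAA")$codon_index  # 1 and 2
#' @export
enumerateCodonInstances <- function(orfs, codon) {
    .checkCodon(codon)
    ids <- orfIds(orfs)
    out <- lapply(ids, function(id) {
        cods <- .orfCodons(orfs, id)
        hit <- which(cods == codon) - 1L
        if (!length(hit)) return(NULL)
        data.frame(orf_id = id, codon_index = hit, codon = codon,
                   start_nt = 3L * hit)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(orf_id = character(), codon_index = integer(),
                          codon = character(), start_nt = integer())
    out
}

.checkCodon <- function(codon) {
    if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
        grepl("[^ACGT]", codon))
        stop("'codon' must be a 3-mer over ACGT, got '", codon, "'")
    invisible(codon)
}
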