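#' @include AllClasses.R
NULL

#' Read and write read sets as FASTA plus a truth sidecar
#'
#' Reads are serialized as plain FASTA; the truth table travels as a
#' separate TSV so that analysis code never sees ground-truth labels in
#' sequence headers.
#'
#' @param x a [ReadSet-class].
#' @param fasta path to the FASTA file.
#' @param truth path to the truth TSV (optional).
#' @param sample_id,depth_m annotation used when reading back.
#' @return `writeReadSet` returns the paths invisibly; `readReadSet`
#'   returns a [ReadSet-class].
#' @export
writeReadSet <- function(x, fasta, truth = NULL) {
    stopifnot(is(x, "ReadSet"))
    Biostrings::writeXStringSet(x@reads, fasta)
    if (!is.null(truth) && nrow(x@truth))
        utils::write.table(x@truth, truth, sep = "\t", quote = FALSE,
            row.names = FALSE)
    invisible(c(fasta = fasta, truth = truth))
}

#' @rdname writeReadSet
#' @export
readReadSet <- function(fasta, truth = NULL, sample_id = "sample1",
                        depth_m = NA_real_) {
    rd <- Biostrings::readDNAStringSet(fasta)
    names(rd) <- sub("\\s.*$", "", names(rd))
    tt <- if (!is.null(truth) && file.exists(truth))
        utils::read.delim(truth, stringsAsFactors = FALSE)
    else data.frame()
    new("ReadSet", sample_id = sample_id, depth_m = depth_m,
        reads = rd, truth = tt)
}

#' Read and write occurrence matrices as TSV
#'
#' Rows are genomes, columns are gene families, cells are integer copy
#' counts; the first column holds genome ids.
#'
#' @param x an [OccurrenceMatrix-class].
#' @param path file path.
#' @return `readOccurrenceMatrix` returns an [OccurrenceMatrix-class].
#' @export
writeOccurrenceMatrix <- function(x, path) {
    stopifnot(is(x, "OccurrenceMatrix"))
    df <- data.frame(genome_id = rownames(x@copies), x@copies,
        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' @rdname writeOccurrenceMatrix
#' @export
readOccurrenceMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
        stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1]]
    new("OccurrenceMatrix", copies = m)
}

#' Read and write coding loci as BED6
#'
#' BED uses 0-based half-open intervals; the `name` column carries the
#' protein or family id, the score column is unused (0), and strand is
#' the sixth column. Internally loci are [GenomicRanges::GRanges]
#' (1-based closed, as usual for Bioconductor); conversion happens at the
#' file boundary.
#'
#' @param gr a `GRanges` with metadata column `protein_id` (or
#'   `family_id`).
#' @param path file path.
#' @return `readBed` returns a `GRanges` with metadata column
#'   `protein_id`.
#' @export
writeBed <- function(gr, path) {
    id <- S4Vectors::mcols(gr)$protein_id
    if (is.null(id)) id <- S4Vectors::mcols(gr)$family_id
    if (is.null(id)) id <- sprintf("feature%05d", seq_along(gr))
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = id,
        score = 0L,
        strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
    df <- utils::read.delim(path, header = FALSE,
        stringsAsFactors = FALSE)
    colnames(df)[seq_len(min(6L, ncol(df)))] <-
        c("chrom", "start", "end", "name", "score", "strand")[
            seq_len(min(6L, ncol(df)))]
    strand <- if ("strand" %in% colnames(df))
        sub("\\.", "*", df$strand) else "*"
    GRanges(seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
        strand = strand,
        protein_id = if ("name" %in% colnames(df)) df$name else
            sprintf("feature%05d", seq_len(nrow(df))))
}

#' Export an abundance matrix as TSV
#'
#' Targets in rows, samples in columns, values in percent of sample
#' reads per Mbp of assembly.
#'
#' @param x an [AbundanceMatrix-class].
#' @param path file path.
#' @export
writeAbundanceMatrix <- function(x, path) {
    a <- SummarizedExperiment::assay(x, "abundance")
    df <- data.frame(target_id = rownames(a), a, check.names = FALSE,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Export a QC report as TSV
#'
#' @param x a [QcReport-class].
#' @param path file path.
#' @export
writeQcReport <- function(x, path) {
    k <- qcCounts(x)
    utils::write.table(
        data.frame(metric = names(k), count = as.integer(k)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
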