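#' @include AllClasses.R
NULL

.dnaScoringMatrix <- function() {
    Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
        baseOnly = TRUE)
}

# score/identity bookkeeping from a PairwiseAlignments object; subject
# coordinates are converted to 0-based half-open
.alignStats <- function(aln) {
    cols <- nchar(as.character(Biostrings::pattern(aln)))
    list(score = Biostrings::score(aln),
         start = start(Biostrings::subject(aln)) - 1L,
         end = end(Biostrings::subject(aln)),
         aln_len = cols,
         identity = Biostrings::nmatch(aln) / cols)
}

#' Optimal local alignment of a read against a contig
#'
#' Smith-Waterman alignment of the read and of its reverse complement
#' against the contig under match +1, mismatch -1, affine gap open -2 /
#' extend -1 (the weights of the BLASTN 1/-1 scheme the recruitment
#' protocol uses). Identity is matches divided by alignment columns, gap
#' columns included in the denominator (the BLAST convention). The
#' higher-scoring strand wins; on a tie the alignment with the leftmost
#' contig start, then the + strand, is returned.
#'
#' @param read nucleotide string (>= 30 bp).
#' @param contig nucleotide string.
#' @return list with `score`, `start`, `end` (0-based half-open on the
#'   contig), `aln_len` (alignment columns), `identity`, `strand`.
#' @examples
#' contig <- strrep("ACGGTTACAGATTACA", 40)
#' read <- substr(contig, 101, 350)
#' localAlign(read, contig)[c("score", "identity", "strand")]
#' @export
localAlign <- function(read, contig) {
    stopifnot(is.character(read), is.character(contig))
    if (nchar(read) < 30L) stop("read must be at least 30 bp")
    mat <- .dnaScoringMatrix()
    fwd <- pairwiseAlignment(read, contig, type = "local",
        substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
    rev <- pairwiseAlignment(reverseComplement1(read), contig,
        type = "local", substitutionMatrix = mat, gapOpening = 2,
        gapExtension = 1)
    f <- .alignStats(fwd); f$strand <- "+"
    r <- .alignStats(rev); r$strand <- "-"
    if (f$score > r$score) f
    else if (r$score > f$score) r
    else if (f$start <= r$start) f
    else r
}

# k-mer seed index of a DNAStringSet, one data.table row per (kmer,
# contig, 1-based position), keyed by kmer
.seedIndex <- function(contigs, k) {
    tabs <- lapply(seq_along(contigs), function(i) {
        s <- as.character(contigs[[i]])
        n <- nchar(s)
        if (n < k) return(NULL)
        data.table::data.table(
            kmer = substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) +
                k - 1L),
            contig = names(contigs)[i],
            cpos = seq_len(n - k + 1L))
    })
    idx <- data.table::rbindlist(tabs)
    if (nrow(idx)) data.table::setkey(idx, kmer)
    idx
}

# candidate (read, contig, strand, diagonal) bands for all reads at
# once, from exact k-mer seed matches; keeps the top `max_bands` bands
# per read by seed count
.seedBandsAll <- function(seqs, seqs_rc, idx, k, stride, max_bands = 4L) {
    qs <- list()
    for (strand in c("+", "-")) {
        ss <- if (strand == "+") seqs else seqs_rc
        for (i in seq_along(ss)) {
            n <- nchar(ss[i])
            if (n < k) next
            rpos <- seq.int(1L, n - k + 1L, by = stride)
            qs[[paste0(strand, i)]] <- data.table::data.table(
                read = i, strand = strand, rpos = rpos,
                kmer = substring(ss[i], rpos, rpos + k - 1L))
        }
    }
    q <- data.table::rbindlist(qs)
    if (!nrow(q)) return(data.table::data.table())
    m <- idx[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(m)) return(data.table::data.table())
    m[, diag := cpos - rpos]
    m[, band := diag %/% 30L]
    bs <- m[, list(nseed = .N, diag0 = as.integer(stats::median(diag))),
        by = c("read", "contig", "strand", "band")]
    data.table::setorderv(bs, c("read", "nseed", "contig", "band"),
        order = c(1L, -1L, 1L, 1L))
    bs[, rank := seq_len(.N), by = "read"]
    bs[rank <= max_bands]
}

#' Recruit metagenome reads to an assembly
#'
#' Aligns each read (pre-filtered by [filterReads()]) against the
#' assembly, keeps the single best-scoring alignment per read, and emits
#' it as a recruit when the alignment is at least `min_aln_len` columns
#' long and at least `min_identity` identical. Recruitment is computed
#' independently per target assembly; no cross-target competition.
#'
#' The default engine localizes candidate alignment windows by exact
#' k-mer seeding on a diagonal-banded index and scores each window with
#' the same optimal Smith-Waterman aligner as [localAlign()], so every
#' emitted hit is an optimal local alignment; `method = "full"` aligns
#' each read against each whole contig and is used to validate the fast
#' path on small instances. Seeding cannot miss alignments in the
#' regime the filters accept (a 200-column, 95%-identity alignment
#' without a single exact 14-mer is vanishingly improbable).
#'
#' @param x a [ReadSet-class] or named [Biostrings::DNAStringSet].
#' @param target a [SagAssembly-class], [Genome-class], or named
#'   [Biostrings::DNAStringSet] of contigs.
#' @param min_aln_len minimum alignment length in columns (default 200).
#' @param min_identity minimum identity fraction (default 0.95).
#' @param method `"seed"` (default) or `"full"`.
#' @param k seed k-mer size (seed method).
#' @param stride spacing of query seed positions in bp (seed method).
#' @return a [GenomicRanges::GRanges] on the target contigs (0-based
#'   half-open intervals are recovered with [hitsTable()]), with metadata
#'   columns `read_id`, `target_id`, `score`, `aln_len`, `identity`.
#' @examples
#' g <- makeGenome(20000, 0.34, seed = 1, genome_id = "gA")
#' rs <- makeMetagenome(
#'     data.frame(genome_id = "gA", relative_abundance = 1,
#'                divergence = 0.02),
#'     list(gA = g), n_reads = 20, read_len_range = c(250, 400), seed = 2)
#' hits <- recruitReads(rs, g)
#' length(hits)
#' @export
recruitReads <- function(x, target, min_aln_len = 200L,
                         min_identity = 0.95,
                         method = c("seed", "full"), k = 14L,
                         stride = 7L) {
    method <- match.arg(method)
    rs <- if (is(x, "ReadSet")) x@reads else x
    ctgs <- targetContigs(target)
    if (length(ctgs) == 0L || sum(width(ctgs)) == 0L)
        stop("empty assembly: nothing to recruit against")
    target_id <- targetId(target)
    cstr <- stats::setNames(as.character(ctgs), names(ctgs))
    mat <- .dnaScoringMatrix()
    seqs <- as.character(rs)
    ids <- names(rs)
    res <- vector("list", length(seqs))

    if (method == "full") {
        for (i in seq_along(seqs)) {
            best <- NULL
            for (cn in names(cstr)) {
                h <- localAlign(seqs[i], cstr[[cn]])
                h$contig <- cn
                best <- .betterHit(best, h)
            }
            res[[i]] <- best
        }
    } else if (length(seqs)) {
        idx <- .seedIndex(ctgs, k)
        seqs_rc <- vapply(seqs, reverseComplement1, "",
            USE.NAMES = FALSE)
        bands <- if (nrow(idx))
            .seedBandsAll(seqs, seqs_rc, idx, k, stride) else
            data.table::data.table()
        if (nrow(bands)) {
            pad <- 60L
            rlen <- nchar(seqs)[bands$read]
            w0 <- pmax(1L, bands$diag0 - pad)
            w1 <- pmin(nchar(cstr)[bands$contig], bands$diag0 + rlen +
                pad)
            wins <- substring(cstr[bands$contig], w0, w1)
            qry <- ifelse(bands$strand == "+", seqs[bands$read],
                seqs_rc[bands$read])
            sc <- pairwiseAlignment(qry, DNAStringSet(wins),
                type = "local", substitutionMatrix = mat,
                gapOpening = 2, gapExtension = 1, scoreOnly = TRUE)
            # fully align, per read, every candidate achieving the
            # read's maximum window score; deterministic tie-breaks
            best_sc <- tapply(sc, bands$read, max)
            winner <- sc >= best_sc[as.character(bands$read)] - 1e-9
            wi <- which(winner)
            aln <- pairwiseAlignment(qry[wi], DNAStringSet(wins[wi]),
                type = "local", substitutionMatrix = mat,
                gapOpening = 2, gapExtension = 1)
            stats_cols <- nchar(as.character(Biostrings::pattern(aln)))
            st <- start(Biostrings::subject(aln)) + w0[wi] - 2L
            en <- end(Biostrings::subject(aln)) + w0[wi] - 1L
            scw <- Biostrings::score(aln)
            idw <- Biostrings::nmatch(aln) / stats_cols
            for (j in seq_along(wi)) {
                b <- wi[j]
                i <- bands$read[b]
                h <- list(score = scw[j], start = st[j], end = en[j],
                    aln_len = stats_cols[j], identity = idw[j],
                    strand = bands$strand[b], contig = bands$contig[b])
                res[[i]] <- .betterHit(res[[i]], h)
            }
        }
    }
    keep <- !vapply(res, is.null, TRUE)
    for (i in which(keep)) {
        if (res[[i]]$aln_len < min_aln_len ||
            res[[i]]$identity < min_identity) {
            keep[i] <- FALSE
        } else res[[i]]$read_id <- ids[i]
    }
    hitsGRanges(res[keep], ctgs, target_id)
}

targetContigs <- function(target) {
    if (is(target, "SagAssembly")) contigs(target)
    else if (is(target, "Genome")) {
        out <- DNAStringSet(as.character(target@sequence))
        names(out) <- genomeId(target)
        out
    } else if (is(target, "DNAStringSet")) target
    else stop("unsupported target type")
}

targetId <- function(target) {
    if (is(target, "SagAssembly")) sagId(target)
    else if (is(target, "Genome")) genomeId(target)
    else "target"
}

# deterministic preference: higher score, then leftmost contig start,
# then + strand, then contig name order
.betterHit <- function(best, h) {
    if (is.null(best)) return(h)
    if (h$score != best$score)
        return(if (h$score > best$score) h else best)
    if (h$start != best$start)
        return(if (h$start < best$start) h else best)
    if (h$strand != best$strand)
        return(if (h$strand == "+") h else best)
    best
}

hitsGRanges <- function(hits, ctgs, target_id) {
    sl <- stats::setNames(width(ctgs), names(ctgs))
    if (!length(hits)) {
        gr <- GRanges(seqinfo = GenomeInfoDb::Seqinfo(names(sl),
            unname(sl)))
        S4Vectors::mcols(gr) <- DataFrame(read_id = character(),
            target_id = character(), score = numeric(),
            aln_len = integer(), identity = numeric())
        return(gr)
    }
    GRanges(
        seqnames = vapply(hits, `[[`, "", "contig"),
        ranges = IRanges::IRanges(
            start = vapply(hits, `[[`, 0, "start") + 1L,
            end = vapply(hits, `[[`, 0, "end")),
        strand = vapply(hits, `[[`, "", "strand"),
        read_id = vapply(hits, `[[`, "", "read_id"),
        target_id = target_id,
        score = vapply(hits, `[[`, 0, "score"),
        aln_len = vapply(hits, `[[`, 0L, "aln_len"),
        identity = vapply(hits, `[[`, 0, "identity"),
        seqlengths = sl)
}

#' Tabulate recruitment hits with 0-based half-open coordinates
#'
#' @param hits a `GRanges` from [recruitReads()].
#' @return data.frame with BED-compatible `start` (0-based) and `end`.
#' @export
hitsTable <- function(hits) {
    data.frame(
        read_id = S4Vectors::mcols(hits)$read_id,
        target_id = S4Vectors::mcols(hits)$target_id,
        contig_id = as.character(GenomicRanges::seqnames(hits)),
        start = GenomicRanges::start(hits) - 1L,
        end = GenomicRanges::end(hits),
        strand = as.character(GenomicRanges::strand(hits)),
        aln_len = S4Vectors::mcols(hits)$aln_len,
        identity = S4Vectors::mcols(hits)$identity,
        score = S4Vectors::mcols(hits)$score,
        stringsAsFactors = FALSE)
}

#' Build a length-normalized abundance matrix from recruitment hits
#'
#' The abundance of a target in a sample is the percentage of the
#' sample's (post-QC) reads recruited to the target, normalized per Mbp
#' of assembly: `100 * n_hits / n_reads / (assembly_length / 1e6)`. This
#' makes partial assemblies of different sizes comparable and is the
#' quantity plotted in recruitment depth-profile heatmaps.
#'
#' @param hits data.frame with one row per recruited read, columns
#'   `sample_id` and `target_id` (e.g. stacked [hitsTable()] outputs with
#'   a `sample_id` column added), or a pre-computed count matrix
#'   (targets x samples).
#' @param assembly_lengths named numeric, bp per target.
#' @param n_reads named numeric, post-QC read count per sample; all
#'   counts must be positive.
#' @param depth_m optional named numeric, sampling depth per sample.
#' @return an [AbundanceMatrix-class].
#' @examples
#' h <- data.frame(sample_id = rep("s1", 100), target_id = "sagA")
#' am <- abundanceMatrix(h, c(sagA = 1e6), c(s1 = 10000))
#' SummarizedExperiment::assay(am)    # 1 %/Mbp
#' @export
abundanceMatrix <- function(hits, assembly_lengths, n_reads,
                            depth_m = NULL) {
    if (any(n_reads <= 0))
        stop("every sample must have a positive read count")
    if (is.matrix(hits)) {
        counts <- hits
    } else {
        stopifnot(all(c("sample_id", "target_id") %in% colnames(hits)))
        bad_t <- setdiff(unique(hits$target_id), names(assembly_lengths))
        if (length(bad_t))
            stop("unregistered target(s): ", paste(bad_t, collapse = ", "))
        bad_s <- setdiff(unique(hits$sample_id), names(n_reads))
        if (length(bad_s))
            stop("unregistered sample(s): ", paste(bad_s, collapse = ", "))
        counts <- unclass(table(
            factor(hits$target_id, levels = names(assembly_lengths)),
            factor(hits$sample_id, levels = names(n_reads))))
    }
    vals <- 100 * sweep(counts, 2L, n_reads[colnames(counts)], "/")
    vals <- sweep(vals, 1L,
        assembly_lengths[rownames(counts)] / 1e6, "/")
    cd <- DataFrame(n_reads = as.numeric(n_reads[colnames(vals)]))
    if (!is.null(depth_m)) cd$depth_m <- as.numeric(depth_m[colnames(vals)])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = vals),
        rowData = DataFrame(assembly_length =
            as.numeric(assembly_lengths[rownames(vals)])),
        colData = cd)
    new("AbundanceMatrix", se)
}
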