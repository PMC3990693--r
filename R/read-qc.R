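#' @include AllClasses.R
NULL

#' Trinucleotide entropy score of a read
#'
#' Complexity score on a 0-100 scale based on the Shannon entropy of the
#' distribution of overlapping 3-mers:
#' `score = 100 * H / log2(min(L - 2, 64))`, where `H` is the entropy in
#' bits and `L` the sequence length. A sequence with a single distinct
#' trimer (a homopolymer) scores 0; one in which all 64 trimers are
#' equally frequent scores 100. Reads scoring below the threshold
#' (default 70) are treated as low-complexity pyrosequencing artifacts.
#'
#' @param sequence nucleotide string (A/C/G/T), length >= 3, no
#'   ambiguity codes.
#' @return numeric score in `[0, 100]`.
#' @examples
#' entropyScore(strrep("A", 200))            # 0
#' entropyScore(strrep("ACGT", 50))          # 33.33
#' @export
entropyScore <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    L <- nchar(sequence)
    if (L < 3L) stop("sequence must be at least 3 bp")
    if (grepl("[^ACGT]", sequence))
        stop("sequence must contain only A/C/G/T (no ambiguity codes)")
    tri <- substring(sequence, seq_len(L - 2L), seq_len(L - 2L) + 2L)
    p <- table(tri) / (L - 2L)
    H <- max(0, -sum(p * log2(p)))   # guard the -0 of a single trimer
    100 * H / log2(min(L - 2L, 64L))
}

#' Remove replicate and duplicate reads
#'
#' Scans reads in input order and keeps the first occurrence of each
#' duplicate class. A read is removed when it is an exact copy of an
#' already retained read, an exact 5' prefix of one, or the exact reverse
#' complement of one (`dup_classes` controls which relations apply;
#' exact-only mode is available because the replicate definition used by
#' pyrosequencing pipelines is not always stated).
#'
#' @param x a [ReadSet-class] or named [Biostrings::DNAStringSet].
#' @param dup_classes subset of `c("exact", "prefix", "revcomp")`.
#' @return list with `reads` (same class as the input, duplicates
#'   dropped, order preserved) and `removed_ids` (character).
#' @examples
#' rs <- Biostrings::DNAStringSet(c(r1 = "ACGTACGTACGT",
#'                                  r2 = "ACGTACGTACGT",
#'                                  r3 = "ACGTACGT"))
#' dedupeReads(rs)$removed_ids   # r2 (exact), r3 (5' prefix)
#' @export
dedupeReads <- function(x, dup_classes = c("exact", "prefix", "revcomp")) {
    dup_classes <- match.arg(dup_classes,
        c("exact", "prefix", "revcomp"), several.ok = TRUE)
    rs <- if (is(x, "ReadSet")) x@reads else x
    seqs <- as.character(rs)
    n <- length(seqs)
    keep <- logical(n)
    retained <- character(0)
    retained_rc <- character(0)
    use_rc <- "revcomp" %in% dup_classes
    for (i in seq_len(n)) {
        dup <- FALSE
        if (length(retained)) {
            if ("exact" %in% dup_classes && seqs[i] %in% retained)
                dup <- TRUE
            if (!dup && "prefix" %in% dup_classes &&
                any(startsWith(retained, seqs[i]) &
                    nchar(retained) > nchar(seqs[i])))
                dup <- TRUE
            if (!dup && use_rc && seqs[i] %in% retained_rc)
                dup <- TRUE
        }
        if (!dup) {
            keep[i] <- TRUE
            retained <- c(retained, seqs[i])
            if (use_rc)
                retained_rc <- c(retained_rc, reverseComplement1(seqs[i]))
        }
    }
    removed <- names(rs)[!keep]
    out <- if (is(x, "ReadSet")) subsetReadSet(x, names(rs)[keep]) else
        rs[keep]
    list(reads = out, removed_ids = removed)
}

subsetReadSet <- function(x, ids) {
    truth <- x@truth
    if (nrow(truth)) truth <- truth[match(ids, truth$read_id), ,
        drop = FALSE]
    rownames(truth) <- NULL
    new("ReadSet", sample_id = x@sample_id, depth_m = x@depth_m,
        reads = x@reads[ids], truth = truth)
}

#' Quality-filter a metagenome read set
#'
#' Applies, in order, the pre-recruitment filters: minimum length,
#' ambiguity (any non-A/C/G/T character), replicate/duplicate removal,
#' and the trinucleotide entropy filter. Each read is counted under the
#' first rule it fails; retained reads are returned unchanged and in
#' input order. The entropy rule targets the low-complexity artifacts of
#' pyrosequencing chemistry and can be disabled for other platforms.
#'
#' @param x a [ReadSet-class] or named [Biostrings::DNAStringSet].
#' @param min_len minimum read length in bp (default 100; must be >= 3).
#' @param min_entropy entropy threshold on the 0-100 scale (default 70).
#' @param drop_ambiguous remove reads containing ambiguity codes.
#' @param dedupe apply [dedupeReads()].
#' @param entropy apply the entropy filter.
#' @param dup_classes duplicate relations, see [dedupeReads()].
#' @return list with `reads` (filtered, same class as input) and
#'   `report` (a [QcReport-class]).
#' @examples
#' rs <- Biostrings::DNAStringSet(c(ok = strrep("ACGGTAGCCTA", 10),
#'                                  low = strrep("A", 150),
#'                                  short = "ACGT"))
#' filterReads(rs)$report
#' @export
filterReads <- function(x, min_len = 100L, min_entropy = 70,
                        drop_ambiguous = TRUE, dedupe = TRUE,
                        entropy = TRUE,
                        dup_classes = c("exact", "prefix", "revcomp")) {
    if (min_len < 3L) stop("'min_len' must be >= 3")
    rs <- if (is(x, "ReadSet")) x@reads else x
    seqs <- as.character(rs)
    n <- length(seqs)
    fate <- rep("retained", n)

    short <- nchar(seqs) < min_len
    fate[short] <- "short"
    pool <- which(!short)

    if (drop_ambiguous && length(pool)) {
        amb <- grepl("[^ACGT]", seqs[pool])
        fate[pool[amb]] <- "ambiguous"
        pool <- pool[!amb]
    }
    if (dedupe && length(pool)) {
        dd <- dedupeReads(rs[pool], dup_classes = dup_classes)
        dup <- names(rs)[pool] %in% dd$removed_ids
        fate[pool[dup]] <- "duplicate"
        pool <- pool[!dup]
    }
    if (entropy && length(pool)) {
        sc <- vapply(seqs[pool], entropyScore, 0, USE.NAMES = FALSE)
        low <- sc < min_entropy
        fate[pool[low]] <- "low_entropy"
        pool <- pool[!low]
    }
    report <- new("QcReport",
        n_input = n,
        n_removed_short = sum(fate == "short"),
        n_removed_ambiguous = sum(fate == "ambiguous"),
        n_removed_duplicate = sum(fate == "duplicate"),
        n_removed_low_entropy = sum(fate == "low_entropy"),
        n_retained = sum(fate == "retained"))
    keep_ids <- names(rs)[fate == "retained"]
    out <- if (is(x, "ReadSet")) subsetReadSet(x, keep_ids) else
        rs[fate == "retained"]
    list(reads = out, report = report)
}
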