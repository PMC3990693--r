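#' @include AllClasses.R
NULL

#' Pairwise identity of two nucleotide sequences
#'
#' Global alignment with free terminal gaps (ends-free), match +1,
#' mismatch -1, gap -2 per gap column. Identity is matches divided by
#' aligned columns, where terminal-gap columns are excluded (so
#' partial-length amplicons are compared over their overlap) and internal
#' gap columns count as mismatching columns. Symmetric.
#'
#' @param a,b nucleotide strings, each at least 200 bp (the intended use
#'   is SSU rRNA amplicons); shorter inputs are rejected.
#' @param min_len minimum input length (default 200; lower it only for
#'   toy examples).
#' @return identity fraction in `[0, 1]`.
#' @examples
#' a <- strrep("ACGGTTACAGATTACA", 20)
#' pairwiseIdentity(a, a)    # 1
#' @export
pairwiseIdentity <- function(a, b, min_len = 200L) {
    stopifnot(is.character(a), is.character(b))
    if (nchar(a) < min_len || nchar(b) < min_len)
        stop("sequences must be at least ", min_len, " bp")
    mat <- .dnaScoringMatrix()
    aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
        substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
    cols <- nchar(as.character(Biostrings::pattern(aln)))
    if (cols == 0L) return(0)
    Biostrings::nmatch(aln) / cols
}

#' Cluster SSU rRNA sequences into phylotypes
#'
#' Greedy centroid clustering at an identity threshold (default 99%):
#' sequences are processed by decreasing length, ties broken by
#' lexicographic id; each sequence joins the first existing phylotype
#' whose representative it matches at identity >= threshold, otherwise it
#' founds a new phylotype with itself as representative. The result is a
#' partition: every input sequence is assigned exactly once.
#'
#' For clouds of sequences that are well separated (within-cloud
#' identities strictly above, between-cloud strictly below the
#' threshold) the partition is independent of input order; chains of
#' sequences straddling the threshold are order-dependent in any greedy
#' scheme.
#'
#' @param sequences data.frame with columns `id`, `seq` and optionally
#'   `site`; or a named [Biostrings::DNAStringSet] (all sites unknown).
#' @param threshold identity threshold in `(0, 1]` (default 0.99).
#' @param min_len passed to [pairwiseIdentity()].
#' @return list with `phylotypes` (data.frame `phylotype_id`,
#'   `representative_id`, `n_members`), `members` (data.frame `id`,
#'   `phylotype_id`, `site`) and `site_counts` (phylotype x site integer
#'   matrix).
#' @examples
#' s <- strrep("ACGGTTACAGATTACAGGAC", 40)
#' d <- data.frame(id = c("x1", "x2"), seq = c(s, s),
#'                 site = c("A", "B"))
#' clusterPhylotypes(d)$phylotypes
#' @export
clusterPhylotypes <- function(sequences, threshold = 0.99,
                              min_len = 200L) {
    if (is(sequences, "DNAStringSet"))
        sequences <- data.frame(id = names(sequences),
            seq = as.character(sequences),
            site = NA_character_, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "seq") %in% colnames(sequences)),
        nrow(sequences) >= 1L, !anyDuplicated(sequences$id))
    if (is.null(sequences$site)) sequences$site <- NA_character_
    if (threshold <= 0 || threshold > 1)
        stop("'threshold' must be in (0, 1]")
    ord <- order(-nchar(sequences$seq), sequences$id, method = "radix")
    sequences <- sequences[ord, , drop = FALSE]

    rep_seq <- character(0)
    rep_id <- character(0)
    assign <- integer(nrow(sequences))
    for (i in seq_len(nrow(sequences))) {
        s <- sequences$seq[i]
        placed <- 0L
        for (j in seq_along(rep_seq)) {
            if (pairwiseIdentity(s, rep_seq[j], min_len = min_len) >=
                threshold) {
                placed <- j
                break
            }
        }
        if (placed == 0L) {
            rep_seq <- c(rep_seq, s)
            rep_id <- c(rep_id, sequences$id[i])
            placed <- length(rep_seq)
        }
        assign[i] <- placed
    }
    pt_ids <- sprintf("PT%03d", seq_along(rep_id))
    members <- data.frame(id = sequences$id,
        phylotype_id = pt_ids[assign],
        site = sequences$site, stringsAsFactors = FALSE)
    phylotypes <- data.frame(phylotype_id = pt_ids,
        representative_id = rep_id,
        n_members = as.integer(table(factor(assign,
            levels = seq_along(rep_id)))),
        stringsAsFactors = FALSE)
    sites <- sort(unique(members$site[!is.na(members$site)]))
    site_counts <- matrix(0L, length(pt_ids), length(sites),
        dimnames = list(pt_ids, sites))
    if (length(sites)) {
        tb <- table(members$phylotype_id,
            factor(members$site, levels = sites))
        site_counts[rownames(tb), ] <- as.integer(tb)
    }
    list(phylotypes = phylotypes, members = members,
         site_counts = site_counts)
}

# nearest integer, halves away from zero (print-style percentages)
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize per-site gene-screening results
#'
#' Produces a screening table in the style of per-station PCR screens of
#' single-cell libraries: for each site, the number of cells screened and,
#' per gene, the number and nearest-integer percentage of gene-positive
#' cells, plus a pooled `Total` row. Percentages are rounded half away
#' from zero.
#'
#' @param detections data.frame with columns `sag_id`, `site`, `depth_m`
#'   and one logical column per gene (e.g. `amoA`, `nirK`).
#' @return data.frame with one row per site plus a `Total` row; columns
#'   `site`, `depth_m`, `n_sags` and `<gene>_n`, `<gene>_pct` per gene.
#' @examples
#' det <- data.frame(sag_id = sprintf("s%03d", 1:119),
#'     site = rep(c("South Atlantic", "North Pacific"), c(67, 52)),
#'     depth_m = rep(c(800, 770), c(67, 52)),
#'     amoA = c(rep(TRUE, 40), rep(FALSE, 27),
#'              rep(TRUE, 42), rep(FALSE, 10)),
#'     nirK = c(rep(TRUE, 32), rep(FALSE, 35),
#'              rep(TRUE, 32), rep(FALSE, 20)))
#' summarizeScreen(det)
#' @export
summarizeScreen <- function(detections) {
    stopifnot(all(c("sag_id", "site") %in% colnames(detections)),
        nrow(detections) >= 1L)
    if (is.null(detections$depth_m)) detections$depth_m <- NA_real_
    genes <- setdiff(colnames(detections),
        c("sag_id", "site", "depth_m"))
    if (!length(genes)) stop("no gene columns found")
    for (g in genes)
        if (!is.logical(detections[[g]]))
            stop("gene column '", g, "' must be logical")

    oneRow <- function(d, site_label, depth) {
        row <- data.frame(site = site_label, depth_m = depth,
            n_sags = nrow(d), stringsAsFactors = FALSE)
        for (g in genes) {
            n_pos <- sum(d[[g]])
            row[[paste0(g, "_n")]] <- n_pos
            row[[paste0(g, "_pct")]] <-
                as.integer(roundHalfUp(100 * n_pos / nrow(d)))
        }
        row
    }
    sites <- unique(detections$site)
    rows <- lapply(sites, function(s) {
        d <- detections[detections$site == s, , drop = FALSE]
        depth <- unique(d$depth_m)
        oneRow(d, s, if (length(depth) == 1L) depth else NA_real_)
    })
    rows <- c(rows, list(oneRow(detections, "Total", NA_real_)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
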