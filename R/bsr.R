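#' @include AllClasses.R
NULL

.aaAlphabet <- "ACDEFGHIKLMNPQRSTVWY"

.checkProtein <- function(x, what = "protein") {
    bad <- grepl(sprintf("[^%s]", .aaAlphabet), x)
    if (any(bad))
        stop(what, " contains non-standard residues (only the 20-letter ",
             "amino-acid alphabet is accepted): ",
             paste(utils::head(which(bad), 3L), collapse = ", "))
    invisible(TRUE)
}

#' Local protein alignment score
#'
#' Optimal Smith-Waterman raw score under BLOSUM62 with affine gap open
#' -11 / extend -1 (the BLASTP default scheme). Symmetric in its
#' arguments. Inputs are restricted to the standard 20-letter alphabet;
#' ambiguous residues such as X are rejected rather than silently scored.
#'
#' @param a,b amino-acid strings (non-empty, standard alphabet).
#' @return numeric raw alignment score.
#' @examples
#' proteinAlignScore("MKV", "MKV")   # 14 = 5 + 5 + 4 on the diagonal
#' @export
proteinAlignScore <- function(a, b) {
    stopifnot(nzchar(a), nzchar(b))
    .checkProtein(a, "sequence 'a'")
    .checkProtein(b, "sequence 'b'")
    Biostrings::pairwiseAlignment(a, b, type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11,
        gapExtension = 1, scoreOnly = TRUE)
}

# best local score of one query against a whole proteome (vectorised:
# the reference set is the pattern, the query the subject)
.bestRefScore <- function(query, ref) {
    if (length(ref) == 0L) return(0)
    sc <- Biostrings::pairwiseAlignment(ref, query, type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11,
        gapExtension = 1, scoreOnly = TRUE)
    max(0, sc)
}

#' BLAST Score Ratio classification of a query proteome
#'
#' For every query protein the self-alignment score and the best local
#' alignment score against each of two reference proteomes are computed;
#' the score ratios (best score / self score, floored at 0) place the
#' protein in one of four classes: `shared_all` when both ratios exceed
#' the threshold, `shared_a_only` / `shared_b_only` when exactly one
#' does, and `unique` otherwise. Ratios above 0.4 correspond to roughly
#' 30% protein identity and are considered homologous; the comparison is
#' strict (`> threshold`).
#'
#' Raw local-alignment scores (not bitscores) are used in both numerator
#' and denominator; the ratio is invariant to that choice as long as the
#' two match. An empty reference proteome yields all-zero scores against
#' it, not an error.
#'
#' @param query named [Biostrings::AAStringSet] (or named character),
#'   non-empty. Exact duplicate sequences can be removed first with
#'   [nonRedundant()].
#' @param ref_a,ref_b reference proteomes ([Biostrings::AAStringSet] or
#'   character; may be empty).
#' @param threshold homology threshold on the score ratio (default 0.4).
#' @return a [S4Vectors::DataFrame] with one row per query protein:
#'   `protein_id`, `self_score`, `score_a`, `score_b`, `ratio_a`,
#'   `ratio_b`, `category`.
#' @examples
#' tri <- makeProteomeTriplet(2, 1, 1, 1, seed = 1)
#' rec <- bsrClassify(tri$query, tri$ref_a, tri$ref_b)
#' table(rec$category)
#' @export
bsrClassify <- function(query, ref_a, ref_b, threshold = 0.4) {
    query <- AAStringSet(query)
    if (length(query) == 0L) stop("query proteome must be non-empty")
    if (is.null(names(query)))
        names(query) <- sprintf("q%04d", seq_along(query))
    ref_a <- AAStringSet(ref_a)
    ref_b <- AAStringSet(ref_b)
    qs <- as.character(query)
    .checkProtein(qs, "query proteome")
    if (length(ref_a)) .checkProtein(as.character(ref_a), "reference A")
    if (length(ref_b)) .checkProtein(as.character(ref_b), "reference B")

    n <- length(query)
    self <- numeric(n); sa <- numeric(n); sb <- numeric(n)
    for (i in seq_len(n)) {
        self[i] <- Biostrings::pairwiseAlignment(qs[i], qs[i],
            type = "local", substitutionMatrix = "BLOSUM62",
            gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
        sa[i] <- .bestRefScore(qs[i], ref_a)
        sb[i] <- .bestRefScore(qs[i], ref_b)
    }
    ra <- pmax(0, sa / self)
    rb <- pmax(0, sb / self)
    category <- ifelse(ra > threshold & rb > threshold, "shared_all",
        ifelse(ra > threshold, "shared_a_only",
            ifelse(rb > threshold, "shared_b_only", "unique")))
    DataFrame(protein_id = names(query), self_score = self,
        score_a = sa, score_b = sb, ratio_a = ra, ratio_b = rb,
        category = category)
}

#' Drop exact duplicate sequences
#'
#' Non-redundant set construction by exact-sequence deduplication,
#' keeping the first occurrence. Clustering-based redundancy removal is
#' deliberately not attempted.
#'
#' @param x a named [Biostrings::XStringSet].
#' @return `x` with later exact duplicates removed.
#' @export
nonRedundant <- function(x) {
    x[!duplicated(as.character(x))]
}

#' Summarize BSR categories
#'
#' @param records output of [bsrClassify()].
#' @return data.frame with one row per category (`n`, `fraction`) plus
#'   attribute-free totals; `fraction_unique` is the share of query
#'   proteins without a homolog in either reference.
#' @examples
#' tri <- makeProteomeTriplet(2, 1, 1, 2, seed = 1)
#' bsrSummary(bsrClassify(tri$query, tri$ref_a, tri$ref_b))
#' @export
bsrSummary <- function(records) {
    lev <- c("shared_all", "shared_a_only", "shared_b_only", "unique")
    if (NROW(records) == 0L)
        return(data.frame(category = character(), n = integer(),
            fraction = numeric()))
    tab <- table(factor(records$category, levels = lev))
    out <- data.frame(category = lev, n = as.integer(tab),
        fraction = as.numeric(tab) / NROW(records),
        stringsAsFactors = FALSE)
    attr(out, "fraction_unique") <- out$fraction[out$category == "unique"]
    out
}
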