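#' @include AllClasses.R
NULL

#' Call genomic islands by the zero-recruitment rule
#'
#' A coding locus is a putative genomic-island protein when no filtered
#' recruitment hit overlaps any part of it: zero recruitment across the
#' entire sequence length. This is a deliberately conservative rule — a
#' single overlapping recruit, even by one base pair, disqualifies the
#' locus — chosen to avoid false-positive island calls. Hits must be the
#' filtered recruits (alignment length and identity thresholds already
#' applied) against the same assembly the loci live on.
#'
#' @param loci a [GenomicRanges::GRanges] of coding loci on assembly
#'   contigs with a metadata column `protein_id` (and optionally
#'   `cog_category`), e.g. from [readBed()] or [codingLoci()].
#' @param hits a [GenomicRanges::GRanges] of filtered recruitment hits
#'   from [recruitReads()] (hits from several samples may be
#'   concatenated to pool metagenomes).
#' @param contigs optional character vector of valid contig names; loci
#'   on unknown contigs raise an error. Defaults to the union of contig
#'   names seen in `loci` and `hits` seqinfo.
#' @return data.frame with `protein_id`, `n_overlapping_recruits`,
#'   `is_island`.
#' @examples
#' loci <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 400),
#'                                protein_id = "p1")
#' hits <- GenomicRanges::GRanges("c1", IRanges::IRanges(395, 600))
#' callIslands(loci, hits, contigs = "c1")   # overlapped: not an island
#' @export
callIslands <- function(loci, hits, contigs = NULL) {
    stopifnot(is(loci, "GRanges"), is(hits, "GRanges"))
    if (is.null(S4Vectors::mcols(loci)$protein_id))
        stop("'loci' must carry a protein_id metadata column")
    known <- contigs
    if (is.null(known))
        known <- union(GenomeInfoDb::seqlevels(loci),
            GenomeInfoDb::seqlevels(hits))
    bad <- setdiff(unique(as.character(GenomicRanges::seqnames(loci))),
        known)
    if (length(bad))
        stop("loci reference unknown contig(s): ",
             paste(bad, collapse = ", "))
    n_overlap <- GenomicRanges::countOverlaps(loci, hits,
        minoverlap = 1L, ignore.strand = TRUE)
    data.frame(protein_id = S4Vectors::mcols(loci)$protein_id,
        n_overlapping_recruits = as.integer(n_overlap),
        is_island = n_overlap == 0L,
        stringsAsFactors = FALSE)
}

#' COG-category enrichment of the island set
#'
#' Tests, per functional category, whether island proteins are
#' over-represented relative to the full coding background using the
#' one-sided hypergeometric tail probability of observing at least the
#' island count in that category, with Benjamini-Hochberg correction
#' across the tested categories. In mesopelagic archaeal islands this
#' flags the replication/recombination/repair (L), cell-wall/membrane
#' biogenesis (M) and defense (V) categories.
#'
#' @param calls output of [callIslands()].
#' @param categories named character vector `protein_id -> cog_category`
#'   (single-letter codes plus `"mixed"`/`"none"`), or a data.frame with
#'   columns `protein_id` and `cog_category`, covering every called
#'   protein.
#' @param alpha significance level on the adjusted p-value (default
#'   0.05).
#' @return data.frame with one row per category present in the
#'   background: counts, `p_value`, `q_value`, `enriched`. When the
#'   island set is empty an empty result is returned with a warning.
#' @examples
#' calls <- data.frame(protein_id = sprintf("p%03d", 1:100),
#'     n_overlapping_recruits = c(rep(0L, 10), rep(5L, 90)),
#'     is_island = c(rep(TRUE, 10), rep(FALSE, 90)))
#' cats <- setNames(c(rep("V", 10), rep(LETTERS[1:9], 10)),
#'                  calls$protein_id)
#' cogEnrichment(calls, cats)
#' @export
cogEnrichment <- function(calls, categories, alpha = 0.05) {
    if (is.data.frame(categories)) {
        stopifnot(all(c("protein_id", "cog_category") %in%
            colnames(categories)))
        categories <- stats::setNames(categories$cog_category,
            categories$protein_id)
    }
    missing_ids <- setdiff(calls$protein_id, names(categories))
    if (length(missing_ids))
        stop("no category for protein(s): ",
             paste(utils::head(missing_ids, 3L), collapse = ", "))
    cat_all <- categories[calls$protein_id]
    cat_isl <- cat_all[calls$is_island]
    if (length(cat_isl) == 0L) {
        warning("island set is empty; no enrichment computed")
        return(data.frame(category = character(),
            n_island_in_cat = integer(), n_island = integer(),
            n_background_in_cat = integer(), n_background = integer(),
            p_value = numeric(), q_value = numeric(),
            enriched = logical()))
    }
    levs <- sort(unique(cat_all))
    n_bg <- length(cat_all)
    n_isl <- length(cat_isl)
    bg_in <- as.integer(table(factor(cat_all, levels = levs)))
    isl_in <- as.integer(table(factor(cat_isl, levels = levs)))
    # P(X >= isl_in) for X ~ Hypergeom(bg_in white, n_bg - bg_in black,
    # n_isl drawn)
    p <- stats::phyper(isl_in - 1L, bg_in, n_bg - bg_in, n_isl,
        lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    data.frame(category = levs, n_island_in_cat = isl_in,
        n_island = n_isl, n_background_in_cat = bg_in,
        n_background = n_bg, p_value = p, q_value = q,
        enriched = q <= alpha, stringsAsFactors = FALSE)
}
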