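#' @include AllClasses.R
NULL

#' Derive a conserved single-copy gene (CSCG) set
#'
#' A family qualifies as a CSCG when it occurs exactly once in at least
#' `ceiling(threshold * n_genomes)` of the source genomes. Genomes with
#' zero or multiple copies both count against a family, so markers prone
#' to duplication or loss are excluded. With the default 98% threshold
#' applied to a domain-level collection of finished genomes this yields
#' the marker set used to score partial single-cell assemblies.
#'
#' The ceiling rule is deliberate: "present exactly once in 98% of
#' genomes" is a count of genomes, and rounding down would admit families
#' absent from more than 2% of them.
#'
#' @param matrix an [OccurrenceMatrix-class] (>= 10 genomes).
#' @param threshold exactly-once prevalence threshold in `(0, 1]`
#'   (default 0.98).
#' @return a [CscgSet-class].
#' @examples
#' m <- makeOccurrenceMatrix(100, n_single_copy = 94, n_accessory = 20,
#'                           seed = 1)
#' deriveCscgs(m)
#' @export
deriveCscgs <- function(matrix, threshold = 0.98) {
    stopifnot(is(matrix, "OccurrenceMatrix"))
    m <- matrix@copies
    if (nrow(m) == 0L || ncol(m) == 0L)
        stop("occurrence matrix must be non-empty")
    if (nrow(m) < 10L)
        stop("CSCG derivation needs at least 10 genomes")
    if (threshold <= 0 || threshold > 1)
        stop("'threshold' must be in (0, 1]")
    need <- ceiling(threshold * nrow(m))
    once <- colSums(m == 1L)
    fams <- colnames(m)[once >= need]
    new("CscgSet", family_ids = fams,
        n_source_genomes = nrow(m), threshold = threshold)
}

#' Estimate assembly completeness from detected markers
#'
#' Genome recovery is the fraction of the CSCG marker set observed in the
#' assembly. Detection is presence/absence: a marker present in multiple
#' copies (a common amplification artifact) counts once.
#'
#' @param detected_families character vector of family ids detected in
#'   the assembly, or a [SagAssembly-class].
#' @param cscgs a non-empty [CscgSet-class].
#' @return completeness fraction in `[0, 1]`.
#' @examples
#' cs <- new("CscgSet", family_ids = paste0("SC", 1:94),
#'           n_source_genomes = 155L, threshold = 0.98)
#' estimateCompleteness(paste0("SC", 1:47), cs)   # 0.5
#' @export
estimateCompleteness <- function(detected_families, cscgs) {
    stopifnot(is(cscgs, "CscgSet"))
    if (length(cscgs@family_ids) == 0L)
        stop("CSCG set is empty; cannot estimate completeness")
    if (is(detected_families, "SagAssembly"))
        detected_families <- detectedFamilies(detected_families)
    length(intersect(unique(detected_families), cscgs@family_ids)) /
        length(cscgs@family_ids)
}

#' Estimate genome size from assembly length and completeness
#'
#' The only estimator consistent with the marker-ratio completeness
#' definition: `assembly_length / completeness`. A completeness of zero
#' leaves the size undefined and is reported as `NA` rather than
#' infinity.
#'
#' @param assembly_length assembled length in bp.
#' @param completeness completeness fraction in `(0, 1]`.
#' @return estimated genome size in bp, or `NA_real_` when completeness
#'   is 0.
#' @examples
#' estimateGenomeSize(1e6, 0.5)   # 2e6
#' @export
estimateGenomeSize <- function(assembly_length, completeness) {
    stopifnot(length(assembly_length) == length(completeness))
    if (any(completeness < 0 | completeness > 1, na.rm = TRUE))
        stop("'completeness' must be in [0, 1]")
    out <- assembly_length / completeness
    out[!is.na(completeness) & completeness == 0] <- NA_real_
    out
}

#' Completeness table for a set of assemblies
#'
#' Convenience wrapper producing one row per assembly with observed and
#' total marker counts, the completeness estimate, and the genome-size
#' estimate.
#'
#' @param assemblies list of [SagAssembly-class] objects, or a named list
#'   `sag_id -> character vector of detected families` together with
#'   `assembly_lengths`.
#' @param cscgs a [CscgSet-class].
#' @param assembly_lengths named numeric, required when `assemblies` is a
#'   list of family-id vectors.
#' @return data.frame with columns `sag_id`, `n_observed`, `n_total`,
#'   `completeness`, `assembly_length`, `genome_size_estimate`.
#' @examples
#' g <- makeGenome(50000, 0.34, seed = 1)
#' loci <- data.frame(family_id = sprintf("SC%04d", 1:94),
#'                    start = round(seq(0, 49500, length.out = 94)))
#' loci$end <- loci$start + 3
#' a <- makeSagAssembly(g, 0.5, n_contigs = 10, family_loci = loci,
#'                      seed = 2)
#' m <- makeOccurrenceMatrix(155, 94, 0, seed = 3)
#' completenessTable(list(a), deriveCscgs(m))
#' @export
completenessTable <- function(assemblies, cscgs, assembly_lengths = NULL) {
    stopifnot(is(cscgs, "CscgSet"))
    rows <- lapply(assemblies, function(a) {
        if (is(a, "SagAssembly")) {
            det <- detectedFamilies(a)
            id <- sagId(a)
            alen <- assemblyLength(a)
        } else {
            det <- a
            id <- NA_character_
            alen <- NA_real_
        }
        comp <- estimateCompleteness(det, cscgs)
        data.frame(sag_id = id,
            n_observed = length(intersect(unique(det), cscgs@family_ids)),
            n_total = length(cscgs@family_ids),
            completeness = comp,
            assembly_length = alen,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(assembly_lengths)) {
        nm <- names(assemblies)
        out$sag_id <- ifelse(is.na(out$sag_id) & !is.null(nm), nm,
            out$sag_id)
        out$assembly_length <- ifelse(is.na(out$assembly_length),
            assembly_lengths[out$sag_id], out$assembly_length)
    }
    out$genome_size_estimate <- estimateGenomeSize(out$assembly_length,
        out$completeness)
    rownames(out) <- NULL
    out
}
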