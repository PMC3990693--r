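#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAString DNAStringSet AAStringSet width
#' @importFrom GenomicRanges GRanges
NULL

#' Genome: a synthetic or reference nucleotide sequence
#'
#' Container for a single genome sequence together with the GC fraction it
#' was generated to have. Genomes are the substrate for SAG assembly
#' simulation, mutation, and metagenome read generation.
#'
#' @slot genome_id single character identifier.
#' @slot sequence a [Biostrings::DNAString] over A/C/G/T.
#' @slot gc_target numeric in (0, 1); the GC fraction the generator aimed
#'   for (realized GC tracks it within binomial noise).
#'
#' @seealso [makeGenome()], [mutateGenome()]
#' @export
setClass("Genome",
    representation(
        genome_id = "character",
        sequence = "DNAString",
        gc_target = "numeric"
    )
)

setValidity("Genome", function(object) {
    msg <- character()
    if (length(object@genome_id) != 1L || !nzchar(object@genome_id))
        msg <- c(msg, "genome_id must be a single non-empty string")
    if (length(object@sequence) < 1000L)
        msg <- c(msg, "sequence must be at least 1000 bp")
    if (length(object@gc_target) != 1L || object@gc_target <= 0 ||
        object@gc_target >= 1)
        msg <- c(msg, "gc_target must be a single value in (0, 1)")
    af <- Biostrings::alphabetFrequency(object@sequence, baseOnly = TRUE)
    if (af[["other"]] > 0L)
        msg <- c(msg, "sequence must contain only A/C/G/T")
    if (length(msg)) msg else TRUE
})

#' SagAssembly: a partial single-cell genome assembly
#'
#' A set of contigs recovered from a source genome, with the gene-family
#' loci that landed wholly inside retained contigs marked as detected.
#' This is the unit of completeness estimation and the target of fragment
#' recruitment.
#'
#' @slot sag_id single character identifier.
#' @slot genome_id identifier of the source genome.
#' @slot contigs named [Biostrings::DNAStringSet]; contig names are unique.
#' @slot contig_offsets integer vector (named as `contigs`): 0-based start
#'   of each contig on the source genome.
#' @slot assembly_length total assembled length in bp.
#' @slot detected_families character vector of gene-family ids whose locus
#'   lies wholly inside a retained contig.
#' @slot loci a [GenomicRanges::GRanges] of family/protein coding loci in
#'   contig coordinates (only loci on retained contigs), with metadata
#'   column `family_id`.
#'
#' @seealso [makeSagAssembly()], [estimateCompleteness()], [recruitReads()]
#' @export
setClass("SagAssembly",
    representation(
        sag_id = "character",
        genome_id = "character",
        contigs = "DNAStringSet",
        contig_offsets = "integer",
        assembly_length = "integer",
        detected_families = "character",
        loci = "GRanges"
    )
)

setValidity("SagAssembly", function(object) {
    msg <- character()
    nm <- names(object@contigs)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "contigs must have unique names")
    if (object@assembly_length != sum(width(object@contigs)))
        msg <- c(msg, "assembly_length must equal total contig width")
    if (length(object@contig_offsets) != length(object@contigs))
        msg <- c(msg, "contig_offsets must parallel contigs")
    if (length(msg)) msg else TRUE
})

#' ReadSet: a metagenome read sample
#'
#' Reads from one metagenome sample, optionally with an out-of-band truth
#' table recording, for every read, its class (clean or one of the junk
#' classes) and, for clean reads, the source genome interval. Truth is
#' carried as a sidecar table, never in the FASTA headers the analysis
#' code parses.
#'
#' @slot sample_id single character sample identifier.
#' @slot depth_m sampling depth in metres (NA allowed).
#' @slot reads named [Biostrings::DNAStringSet]; read ids unique; may
#'   contain N in junk reads.
#' @slot truth a data.frame with one row per read (or zero rows when no
#'   truth is carried): columns `read_id`, `class` (one of clean, short,
#'   ambiguous, duplicate, low_complexity), `genome_id`, `start`, `end`
#'   (0-based half-open on the source genome; NA for junk), `strand`.
#'
#' @seealso [makeMetagenome()], [filterReads()]
#' @export
setClass("ReadSet",
    representation(
        sample_id = "character",
        depth_m = "numeric",
        reads = "DNAStringSet",
        truth = "data.frame"
    )
)

setValidity("ReadSet", function(object) {
    msg <- character()
    nm <- names(object@reads)
    if (length(object@reads) && (is.null(nm) || anyDuplicated(nm)))
        msg <- c(msg, "read ids must be present and unique")
    if (nrow(object@truth)) {
        if (!setequal(object@truth$read_id, nm))
            msg <- c(msg, "truth table must cover exactly the read ids")
    }
    if (length(msg)) msg else TRUE
})

#' QcReport: read filtering accounting
#'
#' Removal counts from [filterReads()]. Every input read is counted once:
#' under the first rule it fails (length, ambiguity, duplicate, entropy)
#' or as retained.
#'
#' @slot n_input,n_retained counts.
#' @slot n_removed_short,n_removed_ambiguous,n_removed_duplicate,n_removed_low_entropy
#'   removal counts per rule.
#' @export
setClass("QcReport",
    representation(
        n_input = "integer",
        n_removed_short = "integer",
        n_removed_ambiguous = "integer",
        n_removed_duplicate = "integer",
        n_removed_low_entropy = "integer",
        n_retained = "integer"
    )
)

setValidity("QcReport", function(object) {
    counts <- c(object@n_input, object@n_removed_short,
        object@n_removed_ambiguous, object@n_removed_duplicate,
        object@n_removed_low_entropy, object@n_retained)
    if (any(counts < 0L))
        return("all counts must be non-negative")
    if (object@n_input != object@n_retained + object@n_removed_short +
        object@n_removed_ambiguous + object@n_removed_duplicate +
        object@n_removed_low_entropy)
        return("counts must reconcile: input = retained + removals")
    TRUE
})

#' OccurrenceMatrix: gene-family copy counts across genomes
#'
#' Integer matrix of copy counts, genomes in rows and gene families in
#' columns, from which conserved single-copy gene (CSCG) sets are derived.
#'
#' @slot copies integer matrix with unique row (genome) and column
#'   (family) names; entries are non-negative copy counts.
#'
#' @seealso [deriveCscgs()], [makeOccurrenceMatrix()]
#' @export
setClass("OccurrenceMatrix",
    representation(copies = "matrix")
)

setValidity("OccurrenceMatrix", function(object) {
    m <- object@copies
    msg <- character()
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "genome (row) names must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msg <- c(msg, "family (column) names must be present and unique")
    if (any(m < 0) || any(m != round(m)))
        msg <- c(msg, "copy counts must be non-negative integers")
    if (length(msg)) msg else TRUE
})

#' CscgSet: a conserved single-copy gene marker set
#'
#' Gene families present exactly once in at least a threshold fraction of
#' the source genomes, used as completeness markers.
#'
#' @slot family_ids character vector of marker family ids (unique).
#' @slot n_source_genomes number of genomes the set was derived from.
#' @slot threshold the exactly-once prevalence threshold (default 0.98).
#'
#' @seealso [deriveCscgs()], [estimateCompleteness()]
#' @export
setClass("CscgSet",
    representation(
        family_ids = "character",
        n_source_genomes = "integer",
        threshold = "numeric"
    )
)

setValidity("CscgSet", function(object) {
    msg <- character()
    if (anyDuplicated(object@family_ids))
        msg <- c(msg, "family_ids must be unique")
    if (object@threshold <= 0 || object@threshold > 1)
        msg <- c(msg, "threshold must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' AbundanceMatrix: length-normalized recruitment abundances
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay,
#' `abundance`: percent of sample reads recruited per Mbp of assembly,
#' targets (assemblies/genomes) in rows and metagenome samples in columns.
#' `rowData` carries `assembly_length` (bp) and `colData` carries
#' `n_reads` (post-QC read count per sample) and optional `depth_m`.
#'
#' @seealso [abundanceMatrix()]
#' @export
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (any(!is.finite(a)) || any(a < 0))
        return("abundance values must be finite and non-negative")
    if (!"assembly_length" %in% colnames(SummarizedExperiment::rowData(object)))
        return("rowData must carry assembly_length")
    if (!"n_reads" %in% colnames(SummarizedExperiment::colData(object)))
        return("colData must carry n_reads")
    TRUE
})
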