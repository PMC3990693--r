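#' @include AllClasses.R
NULL

#' Accessors for sagscope classes
#'
#' Small accessor generics for the package's S4 containers. Slot access
#' via `@` is internal; use these in user code.
#'
#' @param x an object of the documented class.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname accessors
#' @export
setGeneric("sagId", function(x) standardGeneric("sagId"))
#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setGeneric("contigOffsets", function(x) standardGeneric("contigOffsets"))
#' @rdname accessors
#' @export
setGeneric("assemblyLength", function(x) standardGeneric("assemblyLength"))
#' @rdname accessors
#' @export
setGeneric("detectedFamilies", function(x) standardGeneric("detectedFamilies"))
#' @rdname accessors
#' @export
setGeneric("codingLoci", function(x) standardGeneric("codingLoci"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))
#' @rdname accessors
#' @export
setGeneric("readTruth", function(x) standardGeneric("readTruth"))
#' @rdname accessors
#' @export
setGeneric("copyCounts", function(x) standardGeneric("copyCounts"))
#' @rdname accessors
#' @export
setGeneric("cscgFamilies", function(x) standardGeneric("cscgFamilies"))
#' @rdname accessors
#' @export
setGeneric("qcCounts", function(x) standardGeneric("qcCounts"))

#' @rdname accessors
setMethod("genomeId", "Genome", function(x) x@genome_id)
#' @rdname accessors
setMethod("genomeId", "SagAssembly", function(x) x@genome_id)
#' @rdname accessors
setMethod("genomeSequence", "Genome", function(x) x@sequence)
#' @rdname accessors
setMethod("sagId", "SagAssembly", function(x) x@sag_id)
#' @rdname accessors
setMethod("contigs", "SagAssembly", function(x) x@contigs)
#' @rdname accessors
setMethod("contigOffsets", "SagAssembly", function(x) x@contig_offsets)
#' @rdname accessors
setMethod("assemblyLength", "SagAssembly", function(x) x@assembly_length)
#' @rdname accessors
setMethod("detectedFamilies", "SagAssembly", function(x) x@detected_families)
#' @rdname accessors
setMethod("codingLoci", "SagAssembly", function(x) x@loci)
#' @rdname accessors
setMethod("sampleId", "ReadSet", function(x) x@sample_id)
#' @rdname accessors
setMethod("reads", "ReadSet", function(x) x@reads)
#' @rdname accessors
setMethod("readTruth", "ReadSet", function(x) x@truth)
#' @rdname accessors
setMethod("copyCounts", "OccurrenceMatrix", function(x) x@copies)
#' @rdname accessors
setMethod("cscgFamilies", "CscgSet", function(x) x@family_ids)

#' @rdname accessors
setMethod("qcCounts", "QcReport", function(x) {
    c(n_input = x@n_input,
      n_removed_short = x@n_removed_short,
      n_removed_ambiguous = x@n_removed_ambiguous,
      n_removed_duplicate = x@n_removed_duplicate,
      n_removed_low_entropy = x@n_removed_low_entropy,
      n_retained = x@n_retained)
})

#' @rdname accessors
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))
#' @rdname accessors
#' @export
setMethod("length", "Genome", function(x) length(x@sequence))
#' @rdname accessors
#' @export
setMethod("length", "CscgSet", function(x) length(x@family_ids))

setMethod("show", "Genome", function(object) {
    gc <- Biostrings::letterFrequency(object@sequence, "GC",
        as.prob = TRUE)[[1]]
    cat("Genome", object@genome_id, ":", length(object@sequence), "bp,",
        sprintf("GC %.3f (target %.3f)\n", gc, object@gc_target))
})

setMethod("show", "SagAssembly", function(object) {
    cat("SagAssembly", object@sag_id, "from genome", object@genome_id, "\n")
    cat(" ", length(object@contigs), "contigs,",
        object@assembly_length, "bp assembled,",
        length(object@detected_families), "families detected\n")
})

setMethod("show", "ReadSet", function(object) {
    cat("ReadSet", object@sample_id,
        if (!is.na(object@depth_m)) paste0("(", object@depth_m, " m)"),
        ":", length(object@reads), "reads")
    if (nrow(object@truth))
        cat(";", sum(object@truth$class == "clean"), "clean per truth")
    cat("\n")
})

setMethod("show", "QcReport", function(object) {
    k <- qcCounts(object)
    cat("QcReport:", k[["n_input"]], "reads in,",
        k[["n_retained"]], "retained\n")
    cat("  removed: short", k[["n_removed_short"]],
        "| ambiguous", k[["n_removed_ambiguous"]],
        "| duplicate", k[["n_removed_duplicate"]],
        "| low-entropy", k[["n_removed_low_entropy"]], "\n")
})

setMethod("show", "OccurrenceMatrix", function(object) {
    cat("OccurrenceMatrix:", nrow(object@copies), "genomes x",
        ncol(object@copies), "families\n")
})

setMethod("show", "CscgSet", function(object) {
    cat("CscgSet:", length(object@family_ids), "single-copy marker families",
        sprintf("(exactly-once in >= %.0f%% of %d genomes)\n",
            100 * object@threshold, object@n_source_genomes))
})
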