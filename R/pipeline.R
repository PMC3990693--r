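#' @include AllClasses.R rng.R
NULL

#' Default pipeline configuration
#'
#' Returns the full configuration list for [runPipeline()] with every
#' parameter at its default. Analysis thresholds default to the standard
#' recruitment-protocol values: 100 bp / entropy 70 for read QC, 200 bp
#' and 95% identity for recruitment, 0.98 for CSCG derivation, 0.4 for
#' BSR homology and 0.99 for phylotype clustering. Simulation sizes are
#' desk-scale (tens-of-kbp genomes, a few thousand reads per sample) so
#' a full run completes in minutes.
#'
#' @param outdir output directory.
#' @param seed global seed, fanned out per stage with [stageSeed()].
#' @return a named list; see the configuration section of the package
#'   vignette for the schema.
#' @export
defaultConfig <- function(outdir = tempfile("sagscope_run_"), seed = 1L) {
    list(
        seed = as.integer(seed),
        outdir = outdir,
        stages = list(simulate = TRUE, qc = TRUE, completeness = TRUE,
            recruit = TRUE, islands = TRUE, bsr = TRUE,
            phylotype = TRUE),
        simulate = list(
            n_genomes = 3L, genome_length = 50000L, gc = 0.34,
            n_markers = 94L, n_accessory = 50L,
            n_ref_genomes = 60L, dropout = 0.005, dup_rate = 0.005,
            completeness = c(0.3, 0.6, 0.9), n_contigs = 8L,
            n_samples = 3L, n_reads = 1200L,
            read_len_range = c(250L, 450L),
            junk = c(0.03, 0.03, 0.03, 0.03),
            divergence = 0.02,
            n_coding_loci = 40L, n_islands = 5L),
        qc = list(min_len = 100L, min_entropy = 70, dedupe = TRUE,
            entropy = TRUE),
        completeness = list(threshold = 0.98),
        recruit = list(min_aln_len = 200L, min_identity = 0.95),
        islands = list(alpha = 0.05),
        bsr = list(threshold = 0.4, n_shared_all = 10L, n_shared_a = 10L,
            n_shared_b = 10L, n_unique = 10L),
        phylotype = list(threshold = 0.99, n_clouds = 4L,
            per_cloud = 5L))
}

.rangeCheck <- function(errs, val, name, lo, hi, lo_open = FALSE,
                        hi_open = FALSE) {
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        (if (lo_open) val <= lo else val < lo) ||
        (if (hi_open) val >= hi else val > hi)) {
        bounds <- paste0(if (lo_open) "(" else "[", lo, ", ", hi,
            if (hi_open) ")" else "]")
        errs <- c(errs, paste0(name, " must be a number in ", bounds))
    }
    errs
}

#' Validate a pipeline configuration
#'
#' Merges the given configuration over [defaultConfig()], rejects
#' unknown keys, and range-checks every parameter. All problems are
#' collected and reported together.
#'
#' @param config a (possibly partial) configuration list, or a path to a
#'   YAML file containing one.
#' @return the validated, fully merged configuration (invisibly raises
#'   an error listing every violation otherwise).
#' @examples
#' cfg <- validateConfig(list(recruit = list(min_identity = 0.9)))
#' cfg$recruit$min_identity
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a list or a YAML path")
    base <- defaultConfig()
    errs <- character()
    unknown <- setdiff(names(config), names(base))
    if (length(unknown))
        errs <- c(errs, paste0("unknown top-level key(s): ",
            paste(unknown, collapse = ", ")))
    merged <- base
    for (k in intersect(names(config), names(base))) {
        if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
            bad <- setdiff(names(config[[k]]), names(base[[k]]))
            if (length(bad))
                errs <- c(errs, paste0("unknown key(s) in '", k, "': ",
                    paste(bad, collapse = ", ")))
            for (kk in intersect(names(config[[k]]), names(base[[k]])))
                merged[[k]][[kk]] <- config[[k]][[kk]]
        } else {
            merged[[k]] <- config[[k]]
        }
    }
    errs <- .rangeCheck(errs, merged$seed, "seed", 0, 2^31 - 1)
    errs <- .rangeCheck(errs, merged$qc$min_len, "qc$min_len", 3, 2000)
    errs <- .rangeCheck(errs, merged$qc$min_entropy, "qc$min_entropy",
        0, 100)
    errs <- .rangeCheck(errs, merged$completeness$threshold,
        "completeness$threshold", 0, 1, lo_open = TRUE)
    errs <- .rangeCheck(errs, merged$recruit$min_identity,
        "recruit$min_identity", 0, 1)
    errs <- .rangeCheck(errs, merged$recruit$min_aln_len,
        "recruit$min_aln_len", 30, 5000)
    errs <- .rangeCheck(errs, merged$islands$alpha, "islands$alpha",
        0, 1, lo_open = TRUE, hi_open = TRUE)
    errs <- .rangeCheck(errs, merged$bsr$threshold, "bsr$threshold",
        0, 1, hi_open = TRUE)
    errs <- .rangeCheck(errs, merged$phylotype$threshold,
        "phylotype$threshold", 0, 1, lo_open = TRUE)
    sim <- merged$simulate
    errs <- .rangeCheck(errs, sim$genome_length, "simulate$genome_length",
        1000, 5e6)
    errs <- .rangeCheck(errs, sim$divergence, "simulate$divergence",
        0, 0.25)
    if (!is.numeric(sim$junk) || length(sim$junk) != 4L ||
        any(sim$junk < 0) || any(sim$junk >= 1) || sum(sim$junk) >= 0.5)
        errs <- c(errs,
            "simulate$junk must be 4 fractions in [0,1) summing to < 0.5")
    if (any(sim$completeness <= 0) || any(sim$completeness > 1))
        errs <- c(errs, "simulate$completeness values must be in (0, 1]")
    if (length(errs))
        stop("invalid configuration:\n  - ",
            paste(errs, collapse = "\n  - "), call. = FALSE)
    merged
}

.logStage <- function(stage, ...) {
    message(sprintf("[sagscope:%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the stages in dependency order — simulate, read QC, marker
#' completeness, fragment recruitment and abundance, genomic islands
#' with COG enrichment, BLAST Score Ratio classification, phylotyping
#' and gene screening — writing all tabular outputs as TSV, sequences as
#' FASTA and loci as BED under `config$outdir`. Identical configurations
#' (including the seed) reproduce identical outputs byte for byte; the
#' returned manifest records md5 checksums so this is checkable.
#'
#' @param config a configuration list or YAML path; passed through
#'   [validateConfig()].
#' @return the run manifest (list): the config snapshot, per-file md5
#'   checksums, per-stage wall times and package/R versions. Also
#'   written to `manifest.yaml` in the output directory.
#' @examples
#' \donttest{
#' cfg <- defaultConfig(seed = 7)
#' cfg$simulate$n_reads <- 300L
#' mf <- runPipeline(cfg)
#' names(mf$checksums)
#' }
#' @export
runPipeline <- function(config = defaultConfig()) {
    cfg <- validateConfig(config)
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    sim <- cfg$simulate
    timings <- c()
    tick <- function() proc.time()[["elapsed"]]
    state <- new.env()

    runStage <- function(name, fun) {
        if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
        t0 <- tick()
        .logStage(name, "starting")
        fun()
        timings[[name]] <<- round(tick() - t0, 2)
        .logStage(name, sprintf("done in %.2f s", timings[[name]]))
    }

    runStage("simulate", function() {
        s <- stageSeed(cfg$seed, "simulate")
        gl <- sim$genome_length
        gids <- sprintf("genome%02d", seq_len(sim$n_genomes))
        genomes <- lapply(seq_len(sim$n_genomes), function(i)
            makeGenome(gl, sim$gc, seed = s + i, genome_id = gids[i]))
        names(genomes) <- gids

        # marker + coding loci, shared layout across genomes
        marker_ids <- sprintf("SC%04d", seq_len(sim$n_markers))
        mstart <- round(seq(50, gl - 100,
            length.out = sim$n_markers))
        loci <- data.frame(family_id = marker_ids, start = mstart,
            end = mstart + 3)
        cw <- floor(gl / sim$n_coding_loci)
        pstart <- (seq_len(sim$n_coding_loci) - 1L) * cw + 10L
        ploci <- data.frame(
            family_id = sprintf("p%04d", seq_len(sim$n_coding_loci)),
            start = pstart, end = pstart + min(900L, cw - 20L))
        island_idx <- seq_len(sim$n_islands)
        shield <- ploci[island_idx, c("start", "end"), drop = FALSE]

        completeness <- rep_len(sim$completeness, sim$n_genomes)
        assemblies <- lapply(seq_len(sim$n_genomes), function(i)
            makeSagAssembly(genomes[[i]], completeness[i],
                n_contigs = sim$n_contigs,
                family_loci = rbind(loci, ploci), seed = s + 100L + i,
                sag_id = paste0(gids[i], ".sag")))
        names(assemblies) <- vapply(assemblies, sagId, "")

        # depth-structured communities: genome i peaks in sample i
        depths <- round(seq(200, 800, length.out = sim$n_samples))
        readsets <- lapply(seq_len(sim$n_samples), function(j) {
            w <- 0.2 + 0.8 * (seq_len(sim$n_genomes) ==
                ((j - 1L) %% sim$n_genomes + 1L))
            members <- data.frame(genome_id = gids,
                relative_abundance = w / sum(w),
                divergence = sim$divergence)
            makeMetagenome(members, genomes, sim$n_reads,
                read_len_range = sim$read_len_range, junk = sim$junk,
                shielded = stats::setNames(
                    rep(list(shield), sim$n_genomes), gids),
                sample_id = sprintf("sample%02d", j),
                depth_m = depths[j], seed = s + 200L + j)
        })
        names(readsets) <- vapply(readsets, sampleId, "")

        occ <- makeOccurrenceMatrix(sim$n_ref_genomes, sim$n_markers,
            sim$n_accessory, sim$dropout, sim$dup_rate, seed = s + 300L)

        for (i in seq_along(genomes))
            Biostrings::writeXStringSet(
                stats::setNames(DNAStringSet(as.character(
                    genomes[[i]]@sequence)), gids[i]),
                file.path(cfg$outdir, paste0(gids[i], ".fasta")))
        for (a in assemblies) {
            Biostrings::writeXStringSet(contigs(a),
                file.path(cfg$outdir, paste0(sagId(a), ".contigs.fasta")))
            writeBed(codingLoci(a),
                file.path(cfg$outdir, paste0(sagId(a), ".loci.bed")))
        }
        for (r in readsets)
            writeReadSet(r,
                file.path(cfg$outdir, paste0(sampleId(r), ".fasta")),
                file.path(cfg$outdir, paste0(sampleId(r), ".truth.tsv")))
        writeOccurrenceMatrix(occ, file.path(cfg$outdir,
            "occurrence_matrix.tsv"))

        state$genomes <- genomes
        state$assemblies <- assemblies
        state$readsets <- readsets
        state$occ <- occ
        state$island_truth <- ploci$family_id[island_idx]
        state$coding_ids <- ploci$family_id
    })

    runStage("qc", function() {
        state$clean <- lapply(state$readsets, function(r) {
            fr <- filterReads(r, min_len = cfg$qc$min_len,
                min_entropy = cfg$qc$min_entropy,
                dedupe = cfg$qc$dedupe, entropy = cfg$qc$entropy)
            writeQcReport(fr$report, file.path(cfg$outdir,
                paste0(sampleId(r), ".qc.tsv")))
            writeReadSet(fr$reads, file.path(cfg$outdir,
                paste0(sampleId(r), ".clean.fasta")))
            fr$reads
        })
    })

    runStage("completeness", function() {
        cscgs <- deriveCscgs(state$occ,
            threshold = cfg$completeness$threshold)
        tab <- completenessTable(unname(state$assemblies), cscgs)
        utils::write.table(tab, file.path(cfg$outdir,
            "completeness.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        state$cscgs <- cscgs
    })

    runStage("recruit", function() {
        hit_rows <- list()
        state$hits <- list()
        for (a in state$assemblies) {
            state$hits[[sagId(a)]] <- list()
            for (sid in names(state$clean)) {
                h <- recruitReads(state$clean[[sid]], a,
                    min_aln_len = cfg$recruit$min_aln_len,
                    min_identity = cfg$recruit$min_identity)
                state$hits[[sagId(a)]][[sid]] <- h
                ht <- hitsTable(h)
                if (nrow(ht)) ht$sample_id <- sid
                hit_rows[[paste(sagId(a), sid)]] <- ht
                utils::write.table(ht, file.path(cfg$outdir,
                    paste0(sagId(a), ".", sid, ".hits.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
            }
        }
        all_hits <- do.call(rbind,
            hit_rows[vapply(hit_rows, nrow, 0L) > 0])
        alens <- vapply(state$assemblies, assemblyLength, 0L)
        nreads <- vapply(state$clean, length, 0L)
        depths <- vapply(state$readsets, function(r) r@depth_m, 0)
        am <- abundanceMatrix(
            if (is.null(all_hits))
                matrix(0, length(alens), length(nreads),
                    dimnames = list(names(alens), names(nreads)))
            else all_hits[, c("sample_id", "target_id")],
            alens, nreads, depth_m = depths)
        writeAbundanceMatrix(am, file.path(cfg$outdir, "abundance.tsv"))
        state$abundance <- am
    })

    runStage("islands", function() {
        s <- stageSeed(cfg$seed, "islands")
        # COG categories: planted islands biased toward L/M/V, the rest
        # spread over the remaining single-letter categories
        cats <- withSeed(s, {
            x <- sample(c(LETTERS[seq(2, 22)], "none", "mixed"),
                length(state$coding_ids), replace = TRUE)
            names(x) <- state$coding_ids
            x[state$island_truth] <- sample(c("L", "M", "V"),
                length(state$island_truth), replace = TRUE)
            x
        })
        utils::write.table(
            data.frame(protein_id = names(cats), cog_category = cats),
            file.path(cfg$outdir, "cog_categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        for (a in state$assemblies) {
            loci <- codingLoci(a)
            loci <- loci[startsWith(S4Vectors::mcols(loci)$family_id,
                "p")]
            if (!length(loci)) next
            S4Vectors::mcols(loci)$protein_id <-
                S4Vectors::mcols(loci)$family_id
            pooled <- suppressWarnings(do.call(c,
                unname(state$hits[[sagId(a)]])))
            calls <- callIslands(loci, pooled,
                contigs = names(contigs(a)))
            utils::write.table(calls, file.path(cfg$outdir,
                paste0(sagId(a), ".islands.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
            # partial assemblies may retain no shielded locus; an empty
            # island set is a legitimate outcome here
            enr <- suppressWarnings(
                cogEnrichment(calls, cats, alpha = cfg$islands$alpha))
            utils::write.table(enr, file.path(cfg$outdir,
                paste0(sagId(a), ".enrichment.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
        }
    })

    runStage("bsr", function() {
        s <- stageSeed(cfg$seed, "bsr")
        tri <- makeProteomeTriplet(cfg$bsr$n_shared_all,
            cfg$bsr$n_shared_a, cfg$bsr$n_shared_b, cfg$bsr$n_unique,
            seed = s)
        Biostrings::writeXStringSet(tri$query,
            file.path(cfg$outdir, "query.faa"))
        Biostrings::writeXStringSet(tri$ref_a,
            file.path(cfg$outdir, "ref_a.faa"))
        Biostrings::writeXStringSet(tri$ref_b,
            file.path(cfg$outdir, "ref_b.faa"))
        rec <- bsrClassify(nonRedundant(tri$query), tri$ref_a, tri$ref_b,
            threshold = cfg$bsr$threshold)
        utils::write.table(as.data.frame(rec),
            file.path(cfg$outdir, "bsr.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        utils::write.table(bsrSummary(rec),
            file.path(cfg$outdir, "bsr_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
    })

    runStage("phylotype", function() {
        s <- stageSeed(cfg$seed, "phylotype")
        cl <- makeSsuClouds(cfg$phylotype$n_clouds,
            cfg$phylotype$per_cloud, seed = s)
        res <- clusterPhylotypes(cl[, c("id", "seq", "site")],
            threshold = cfg$phylotype$threshold)
        utils::write.table(res$members, file.path(cfg$outdir,
            "phylotype_members.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        utils::write.table(res$phylotypes, file.path(cfg$outdir,
            "phylotypes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        det <- withSeed(s + 1L, data.frame(
            sag_id = cl$id, site = cl$site,
            depth_m = ifelse(cl$site == "siteA", 800, 770),
            amoA = stats::runif(nrow(cl)) < 0.7,
            nirK = stats::runif(nrow(cl)) < 0.55))
        utils::write.table(summarizeScreen(det), file.path(cfg$outdir,
            "screen_summary.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
    })

    files <- sort(setdiff(list.files(cfg$outdir), "manifest.yaml"))
    manifest <- list(
        config = cfg,
        checksums = as.list(tools::md5sum(
            file.path(cfg$outdir, files))),
        wall_time_s = as.list(timings),
        versions = list(
            sagscope = as.character(utils::packageVersion("sagscope")),
            R = paste(R.version$major, R.version$minor, sep = ".")))
    names(manifest$checksums) <- files
    yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
    invisible(manifest)
}
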