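#' @include AllClasses.R rng.R
NULL

#' Generate a random genome with a target GC content
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc_target` (G and C
#' equiprobable, likewise A and T), so realized GC concentrates around the
#' target with binomial noise. Deterministic for a fixed seed.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc_target target GC fraction, in `[0.2, 0.8]`.
#' @param seed integer seed.
#' @param genome_id identifier for the genome.
#' @return a [Genome-class] object.
#' @examples
#' g <- makeGenome(10000, gc_target = 0.34, seed = 1)
#' g
#' @export
makeGenome <- function(length, gc_target, seed, genome_id = "genome1") {
    if (!is.numeric(length) || length < 1000)
        stop("'length' must be >= 1000 bp")
    if (!is.numeric(gc_target) || gc_target < 0.2 || gc_target > 0.8)
        stop("'gc_target' must be in [0.2, 0.8]")
    seq <- withSeed(seed, randomDna(as.integer(length), gc_target))
    new("Genome", genome_id = genome_id, sequence = DNAString(seq),
        gc_target = gc_target)
}

#' Mutate a genome by random substitutions
#'
#' Produces a substitution-only copy: each base is replaced, independently
#' with probability `divergence`, by one of the three other bases chosen
#' uniformly. Length is preserved and indels are never introduced, so the
#' realized Hamming divergence is binomially distributed around
#' `divergence`. This models the nucleotide divergence between a
#' population sampled by a metagenome and a reference assembly, the
#' quantity that the recruitment identity filter acts on.
#'
#' @param genome a [Genome-class].
#' @param divergence expected per-base substitution rate, in `[0, 0.25]`.
#' @param seed integer seed.
#' @param genome_id identifier for the mutated copy (default appends
#'   `.mut` to the source id).
#' @return a [Genome-class] of the same length.
#' @examples
#' g <- makeGenome(10000, 0.34, seed = 1)
#' m <- mutateGenome(g, 0.02, seed = 2)
#' @export
mutateGenome <- function(genome, divergence, seed,
                         genome_id = paste0(genomeId(genome), ".mut")) {
    stopifnot(is(genome, "Genome"))
    if (!is.numeric(divergence) || divergence < 0 || divergence > 0.25)
        stop("'divergence' must be in [0, 0.25]")
    s <- as.character(genome@sequence)
    if (divergence > 0) {
        s <- withSeed(seed, mutateDnaString(s, divergence))
    }
    new("Genome", genome_id = genome_id, sequence = DNAString(s),
        gc_target = genome@gc_target)
}

# substitution-only mutation of a DNA character string; runs inside a
# withSeed() block of the caller
mutateDnaString <- function(s, divergence) {
    n <- nchar(s)
    nmut <- stats::rbinom(1L, n, divergence)
    if (nmut == 0L) return(s)
    pos <- sample.int(n, nmut)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bases <- c("A", "C", "G", "T")
    for (i in pos) {
        ch[i] <- sample(bases[bases != ch[i]], 1L)
    }
    paste(ch, collapse = "")
}

#' Simulate a partial single-cell genome assembly
#'
#' Draws `n_contigs` disjoint substrings of the source genome whose total
#' length is `completeness` times the genome length (up to contig-boundary
#' granularity), emulating the uneven partial recovery characteristic of
#' MDA-amplified single cells. Gene families whose locus lies wholly
#' inside a retained contig are recorded as detected; loci are re-expressed
#' in contig coordinates so downstream recruitment and island calling see
#' only the assembly.
#'
#' @param genome a [Genome-class].
#' @param completeness fraction of the genome to retain, in `(0, 1]`.
#' @param n_contigs number of contigs (>= 1).
#' @param family_loci `NULL`, or a data.frame with columns `family_id`,
#'   `start`, `end` giving 0-based half-open loci on the genome.
#' @param seed integer seed.
#' @param sag_id identifier for the assembly.
#' @return a [SagAssembly-class].
#' @examples
#' g <- makeGenome(50000, 0.34, seed = 1)
#' loci <- data.frame(family_id = paste0("fam", 1:10),
#'                    start = seq(1000, 46000, by = 5000))
#' loci$end <- loci$start + 900
#' a <- makeSagAssembly(g, completeness = 0.5, n_contigs = 5,
#'                      family_loci = loci, seed = 2)
#' a
#' @export
makeSagAssembly <- function(genome, completeness, n_contigs = 10L,
                            family_loci = NULL, seed = 1L,
                            sag_id = paste0(genomeId(genome), ".sag")) {
    stopifnot(is(genome, "Genome"))
    if (!is.numeric(completeness) || completeness <= 0 || completeness > 1)
        stop("'completeness' must be in (0, 1]")
    n_contigs <- as.integer(n_contigs)
    if (n_contigs < 1L) stop("'n_contigs' must be >= 1")
    L <- length(genome@sequence)
    total <- max(1L, as.integer(round(completeness * L)))
    if (total < n_contigs)
        stop("completeness x genome length (", total,
             " bp) is smaller than n_contigs")
    placement <- withSeed(seed, {
        # split retained length into n parts >= 1, then scatter the
        # unretained remainder into the n + 1 gaps
        parts <- if (n_contigs == 1L) total else {
            cuts <- sort(sample.int(total - 1L, n_contigs - 1L))
            diff(c(0L, cuts, total))
        }
        slack <- L - total
        gaps <- as.vector(stats::rmultinom(1L, slack,
            rep(1 / (n_contigs + 1), n_contigs + 1L)))
        starts0 <- cumsum(gaps[seq_len(n_contigs)]) +
            c(0L, cumsum(parts[-n_contigs]))
        list(starts0 = starts0, widths = parts)
    })
    starts0 <- placement$starts0          # 0-based starts on the genome
    widths <- placement$widths
    gstr <- as.character(genome@sequence)
    contig_names <- sprintf("%s_c%03d", sag_id, seq_len(n_contigs))
    seqs <- substring(gstr, starts0 + 1L, starts0 + widths)
    contigs <- DNAStringSet(seqs)
    names(contigs) <- contig_names

    detected <- character()
    loci_gr <- GRanges()
    if (!is.null(family_loci) && nrow(family_loci)) {
        stopifnot(all(c("family_id", "start", "end") %in%
            colnames(family_loci)))
        fl <- IRanges::IRanges(start = family_loci$start + 1L,
            end = family_loci$end)
        cr <- IRanges::IRanges(start = starts0 + 1L, width = widths)
        hit <- IRanges::findOverlaps(fl, cr, type = "within")
        detected <- unique(family_loci$family_id[S4Vectors::queryHits(hit)])
        if (length(hit)) {
            qi <- S4Vectors::queryHits(hit)
            si <- S4Vectors::subjectHits(hit)
            loci_gr <- GRanges(
                seqnames = contig_names[si],
                ranges = IRanges::IRanges(
                    start = IRanges::start(fl)[qi] - starts0[si],
                    end = IRanges::end(fl)[qi] - starts0[si]),
                strand = "*",
                family_id = family_loci$family_id[qi],
                seqlengths = stats::setNames(widths, contig_names))
        }
    }
    new("SagAssembly", sag_id = sag_id, genome_id = genomeId(genome),
        contigs = contigs,
        contig_offsets = stats::setNames(as.integer(starts0), contig_names),
        assembly_length = sum(as.integer(widths)),
        detected_families = detected, loci = loci_gr)
}

#' Simulate a metagenome read sample from a community
#'
#' Clean reads are drawn from the community genomes in proportion to
#' member relative abundance, mutated at the member's divergence, and
#' never sampled from shielded intervals (the device used to plant
#' metagenome-invisible genomic islands). Junk reads emulating
#' pyrosequencing artifacts are appended according to `junk`: too-short
#' reads (< 100 bp), reads containing ambiguity codes (N), exact
#' duplicates of earlier clean reads, and low-complexity reads built from
#' long homopolymer runs. A truth table records each read's class and,
#' for clean reads, the source interval; it is carried out-of-band and
#' never encoded in FASTA headers.
#'
#' Reads are generated so that no read other than an intentional
#' duplicate collides with an earlier read under the duplicate relations
#' used by [dedupeReads()] (exact copy, 5' prefix, reverse complement);
#' the truth table therefore reconciles exactly with [filterReads()]
#' accounting when clean read lengths are at least the QC length cutoff.
#'
#' @param members data.frame with columns `genome_id`,
#'   `relative_abundance` (summing to 1), `divergence` (each in
#'   `[0, 0.25]`).
#' @param genomes named list of [Genome-class] objects covering every
#'   `genome_id` in `members`.
#' @param n_reads total number of reads to emit (clean + junk).
#' @param read_len_range length-2 numeric, clean read length range in bp,
#'   within `[30, 2000]`.
#' @param junk length-4 numeric `(frac_short, frac_ambiguous,
#'   frac_duplicate, frac_low_complexity)`, each in `[0, 1)`, summing to
#'   less than 0.5.
#' @param shielded named list: `genome_id` -> data.frame(`start`, `end`)
#'   of 0-based half-open intervals excluded from read generation.
#' @param sample_id,depth_m sample annotation.
#' @param seed integer seed.
#' @return a [ReadSet-class] with a full truth table.
#' @examples
#' g <- makeGenome(50000, 0.34, seed = 1, genome_id = "gA")
#' rs <- makeMetagenome(
#'     members = data.frame(genome_id = "gA", relative_abundance = 1,
#'                          divergence = 0.02),
#'     genomes = list(gA = g), n_reads = 100, seed = 3)
#' rs
#' @export
makeMetagenome <- function(members, genomes, n_reads,
                           read_len_range = c(100L, 800L),
                           junk = c(0, 0, 0, 0),
                           shielded = list(),
                           sample_id = "sample1", depth_m = NA_real_,
                           seed = 1L) {
    if (!is.data.frame(members) || nrow(members) == 0L)
        stop("'members' must be a non-empty data.frame")
    stopifnot(all(c("genome_id", "relative_abundance", "divergence") %in%
        colnames(members)))
    if (abs(sum(members$relative_abundance) - 1) > 1e-9)
        stop("relative abundances must sum to 1")
    if (any(members$divergence < 0 | members$divergence > 0.25))
        stop("divergence must be in [0, 0.25]")
    if (length(junk) != 4L || any(junk < 0) || any(junk >= 1) ||
        sum(junk) >= 0.5)
        stop("'junk' must be 4 fractions in [0, 1) summing to < 0.5")
    if (read_len_range[1] < 30 || read_len_range[2] > 2000 ||
        read_len_range[1] > read_len_range[2])
        stop("'read_len_range' must be within [30, 2000]")
    if (!all(members$genome_id %in% names(genomes)))
        stop("every member genome_id must be present in 'genomes'")
    for (gid in names(shielded)) {
        si <- shielded[[gid]]
        if (is.null(si) || !nrow(si)) next
        L <- length(genomes[[gid]]@sequence)
        si <- si[order(si$start), , drop = FALSE]
        if (any(si$start < 0) || any(si$end > L) || any(si$start >= si$end))
            stop("shielded intervals out of genome bounds for ", gid)
        if (nrow(si) > 1L && any(si$start[-1L] < si$end[-nrow(si)]))
            stop("shielded intervals must be non-overlapping for ", gid)
    }
    n_reads <- as.integer(n_reads)
    n_junk <- as.integer(round(junk * n_reads))
    n_clean <- n_reads - sum(n_junk)
    if (n_clean < 0L) stop("junk fractions leave no clean reads")
    if (n_junk[3] > 0L && n_clean == 0L)
        stop("duplicate junk reads require at least one clean read")

    gstr <- vapply(genomes, function(g) as.character(g@sequence), "")
    glen <- nchar(gstr)

    out <- withSeed(seed, {
        seqs <- character(n_reads)
        cls <- character(n_reads)
        src_g <- rep(NA_character_, n_reads)
        src_s <- rep(NA_integer_, n_reads)
        src_e <- rep(NA_integer_, n_reads)
        src_str <- rep(NA_character_, n_reads)
        seen <- new.env(hash = TRUE, parent = emptyenv())
        k <- 0L

        collides <- function(s) {
            if (!is.null(seen[[s]])) return(TRUE)
            rc <- reverseComplement1(s)
            if (!is.null(seen[[rc]])) return(TRUE)
            if (k > 0L && any(startsWith(seqs[seq_len(k)], s))) return(TRUE)
            FALSE
        }
        emit <- function(s, class, g = NA_character_, st = NA_integer_,
                         en = NA_integer_, strand = NA_character_) {
            k <<- k + 1L
            seqs[k] <<- s
            cls[k] <<- class
            src_g[k] <<- g; src_s[k] <<- st; src_e[k] <<- en
            src_str[k] <<- strand
            seen[[s]] <- TRUE
        }

        midx <- if (nrow(members) == 1L) rep(1L, n_clean) else
            sample.int(nrow(members), n_clean, replace = TRUE,
                prob = members$relative_abundance)
        lens <- sampleRange(read_len_range[1], read_len_range[2],
            n_clean)
        for (i in seq_len(n_clean)) {
            m <- midx[i]
            gid <- members$genome_id[m]
            div <- members$divergence[m]
            L <- glen[[gid]]
            len <- min(lens[i], L)
            sh <- shielded[[gid]]
            repeat {
                st <- sample.int(L - len + 1L, 1L) - 1L  # 0-based
                en <- st + len
                if (!is.null(sh) && nrow(sh) &&
                    any(st < sh$end & en > sh$start)) next
                s <- substr(gstr[[gid]], st + 1L, en)
                if (div > 0) s <- mutateDnaString(s, div)
                strand <- sample(c("+", "-"), 1L)
                if (strand == "-") s <- reverseComplement1(s)
                if (collides(s)) next
                emit(s, "clean", gid, st, en, strand)
                break
            }
        }
        for (i in seq_len(n_junk[1])) {
            repeat {
                s <- randomDna(sampleRange(30L, 99L))
                if (!collides(s)) break
            }
            emit(s, "short")
        }
        for (i in seq_len(n_junk[2])) {
            len <- sampleRange(max(100L, read_len_range[1]),
                max(100L, read_len_range[2]))
            s <- randomDna(len)
            pos <- sample.int(len, sample(1:3, 1L))
            for (p in pos) substr(s, p, p) <- "N"
            emit(s, "ambiguous")
        }
        clean_idx <- which(cls[seq_len(k)] == "clean")
        for (i in seq_len(n_junk[3])) {
            j <- clean_idx[sample.int(length(clean_idx), 1L)]
            k <- k + 1L
            seqs[k] <- seqs[j]
            cls[k] <- "duplicate"
        }
        for (i in seq_len(n_junk[4])) {
            repeat {
                len <- sampleRange(max(100L, read_len_range[1]),
                    max(100L, read_len_range[2]))
                nrun <- sample(2:4, 1L)
                rl <- as.vector(stats::rmultinom(1L, len - nrun * 20L,
                    rep(1 / nrun, nrun))) + 20L
                s <- paste(mapply(strrep, sample(c("A", "C", "G", "T"),
                    nrun, replace = TRUE), rl), collapse = "")
                if (!collides(s)) break
            }
            emit(s, "low_complexity")
        }
        list(seqs = seqs, cls = cls, g = src_g, s = src_s, e = src_e,
             strand = src_str)
    })

    ids <- sprintf("read_%06d", seq_len(n_reads))
    rd <- DNAStringSet(out$seqs)
    names(rd) <- ids
    truth <- data.frame(read_id = ids, class = out$cls,
        genome_id = out$g, start = out$s, end = out$e,
        strand = out$strand, stringsAsFactors = FALSE)
    new("ReadSet", sample_id = sample_id, depth_m = depth_m,
        reads = rd, truth = truth)
}

#' Simulate a genome-by-family occurrence matrix
#'
#' Emulates the copy-count structure of finished reference genomes from
#' which conserved single-copy marker sets are derived: `n_single_copy`
#' families are present exactly once in every genome, except for
#' independent dropout (copy 0) and duplication (copy 2) events at the
#' given per-cell rates; `n_accessory` families are present in a random
#' subset of genomes, with per-family prevalence drawn uniformly from
#' 0.05-0.8.
#'
#' @param n_genomes number of genomes (>= 10).
#' @param n_single_copy,n_accessory family counts.
#' @param dropout,dup_rate per-genome-per-family event probabilities.
#' @param seed integer seed.
#' @return an [OccurrenceMatrix-class]; planted single-copy families are
#'   named `SC...`, accessory families `ACC...`.
#' @examples
#' m <- makeOccurrenceMatrix(155, n_single_copy = 94, n_accessory = 50,
#'                           dropout = 0.005, dup_rate = 0.005, seed = 1)
#' m
#' @export
makeOccurrenceMatrix <- function(n_genomes, n_single_copy = 94L,
                                 n_accessory = 50L, dropout = 0,
                                 dup_rate = 0, seed = 1L) {
    n_genomes <- as.integer(n_genomes)
    if (n_genomes < 10L) stop("'n_genomes' must be >= 10")
    stopifnot(dropout >= 0, dropout < 1, dup_rate >= 0, dup_rate < 1)
    copies <- withSeed(seed, {
        sc <- matrix(1L, n_genomes, n_single_copy)
        u <- matrix(stats::runif(n_genomes * n_single_copy),
            n_genomes, n_single_copy)
        sc[u < dropout] <- 0L
        sc[u >= dropout & u < dropout + dup_rate] <- 2L
        acc <- matrix(0L, n_genomes, n_accessory)
        if (n_accessory > 0L) {
            prev <- stats::runif(n_accessory, 0.05, 0.8)
            for (j in seq_len(n_accessory))
                acc[, j] <- stats::rbinom(n_genomes, 1L, prev[j])
        }
        cbind(sc, acc)
    })
    rownames(copies) <- sprintf("g%04d", seq_len(n_genomes))
    colnames(copies) <- c(
        if (n_single_copy > 0L) sprintf("SC%04d", seq_len(n_single_copy)),
        if (n_accessory > 0L) sprintf("ACC%04d", seq_len(n_accessory)))
    new("OccurrenceMatrix", copies = copies)
}

# substitute a fraction of residues with different random residues
mutateProteinString <- function(s, rate) {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    nmut <- max(1L, stats::rbinom(1L, n, rate))
    pos <- sample.int(n, min(nmut, n))
    for (i in pos) ch[i] <- sample(aa[aa != ch[i]], 1L)
    paste(ch, collapse = "")
}

#' Simulate a query proteome and two reference proteomes with known
#' homology structure
#'
#' Builds a query protein set partitioned into four truth categories:
#' families shared with both references, with reference A only, with
#' reference B only, and unique to the query. Shared families are planted
#' as high-identity homologs (about 90% amino-acid identity) in the
#' designated reference(s); unique proteins are random sequences absent
#' from both. This is the ground truth for BLAST Score Ratio recovery
#' tests.
#'
#' @param n_shared_all,n_shared_a,n_shared_b,n_unique family counts per
#'   category (total >= 1).
#' @param seed integer seed.
#' @param len_range protein length range (residues).
#' @return a list with elements `query`, `ref_a`, `ref_b` (named
#'   [Biostrings::AAStringSet]s) and `truth` (data.frame `protein_id`,
#'   `category`).
#' @examples
#' tri <- makeProteomeTriplet(10, 10, 10, 10, seed = 1)
#' table(tri$truth$category)
#' @export
makeProteomeTriplet <- function(n_shared_all, n_shared_a, n_shared_b,
                                n_unique, seed = 1L,
                                len_range = c(150L, 300L)) {
    counts <- c(n_shared_all, n_shared_a, n_shared_b, n_unique)
    if (any(counts < 0) || sum(counts) < 1)
        stop("category counts must be >= 0 with total >= 1")
    cats <- rep(c("shared_all", "shared_a_only", "shared_b_only", "unique"),
        counts)
    n <- length(cats)
    res <- withSeed(seed, {
        q <- character(n); ra <- character(); rb <- character()
        for (i in seq_len(n)) {
            q[i] <- randomProtein(sampleRange(len_range[1],
                len_range[2]))
            if (cats[i] %in% c("shared_all", "shared_a_only"))
                ra <- c(ra, mutateProteinString(q[i], 0.10))
            if (cats[i] %in% c("shared_all", "shared_b_only"))
                rb <- c(rb, mutateProteinString(q[i], 0.10))
        }
        list(q = q, ra = ra, rb = rb)
    })
    query <- AAStringSet(res$q)
    names(query) <- sprintf("q%04d", seq_len(n))
    ref_a <- AAStringSet(res$ra)
    if (length(ref_a)) names(ref_a) <- sprintf("a%04d", seq_along(ref_a))
    ref_b <- AAStringSet(res$rb)
    if (length(ref_b)) names(ref_b) <- sprintf("b%04d", seq_along(ref_b))
    list(query = query, ref_a = ref_a, ref_b = ref_b,
         truth = data.frame(protein_id = names(query), category = cats,
             stringsAsFactors = FALSE))
}

#' Simulate SSU rRNA sequence clouds
#'
#' Generates `n_clouds` well-separated mutational clouds of SSU-like
#' sequences: cloud centres differ from each other by at least roughly
#' `between` substitutions per base, and members differ from their
#' centre by at most `within`. Sequences are assigned alternately to the
#' given sites. Used as ground truth for phylotype clustering.
#'
#' @param n_clouds number of clouds.
#' @param per_cloud members per cloud (single value or vector).
#' @param seed integer seed.
#' @param length sequence length in bp (default 1200, partial SSU
#'   amplicon scale).
#' @param within maximum within-cloud divergence (per-base substitution
#'   rate from the centre).
#' @param between divergence between cloud centres.
#' @param sites character vector of site labels to cycle through.
#' @return data.frame with columns `id`, `seq`, `site`, `cloud`.
#' @examples
#' cl <- makeSsuClouds(4, 5, seed = 1)
#' table(cl$cloud)
#' @export
makeSsuClouds <- function(n_clouds, per_cloud, seed = 1L, length = 1200L,
                          within = 0.004, between = 0.05,
                          sites = c("siteA", "siteB")) {
    stopifnot(n_clouds >= 1, all(per_cloud >= 1))
    per_cloud <- rep_len(per_cloud, n_clouds)
    withSeed(seed, {
        base <- randomDna(length, 0.52)
        centres <- character(n_clouds)
        centres[1] <- base
        for (i in seq_len(n_clouds)[-1])
            centres[i] <- mutateDnaString(base, between * (i - 1))
        rows <- list()
        k <- 0L
        for (i in seq_len(n_clouds)) {
            for (j in seq_len(per_cloud[i])) {
                k <- k + 1L
                s <- if (j == 1L) centres[i] else
                    mutateDnaString(centres[i], stats::runif(1, 0, within))
                rows[[k]] <- data.frame(
                    id = sprintf("ssu_%02d_%02d", i, j), seq = s,
                    site = sites[(k - 1L) %% base::length(sites) + 1L],
                    cloud = i, stringsAsFactors = FALSE)
            }
        }
        do.call(rbind, rows)
    })
}
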