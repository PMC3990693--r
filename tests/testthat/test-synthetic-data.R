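test_that("makeGenome hits its GC target and is seed-deterministic", {
    g <- makeGenome(10000, gc_target = 0.34, seed = 1)
    gc <- Biostrings::letterFrequency(genomeSequence(g), "GC",
        as.prob = TRUE)[[1]]
    expect_gte(gc, 0.31)
    expect_lte(gc, 0.37)
    g2 <- makeGenome(10000, gc_target = 0.34, seed = 1)
    expect_identical(as.character(genomeSequence(g)),
        as.character(genomeSequence(g2)))
    expect_false(identical(
        as.character(genomeSequence(makeGenome(10000, 0.34, seed = 2))),
        as.character(genomeSequence(g))))
})

test_that("makeGenome base counts stay within 3 binomial sd", {
    g <- makeGenome(50000, gc_target = 0.50, seed = 7)
    counts <- Biostrings::alphabetFrequency(genomeSequence(g),
        baseOnly = TRUE)[c("A", "C", "G", "T")]
    sd3 <- 3 * sqrt(50000 * 0.25 * 0.75)
    expect_true(all(abs(counts - 12500) <= sd3))
})

test_that("makeGenome rejects out-of-range parameters", {
    expect_error(makeGenome(500, 0.34, seed = 1), "1000")
    expect_error(makeGenome(10000, 0.1, seed = 1), "gc_target")
    expect_error(makeGenome(10000, 0.9, seed = 1), "gc_target")
})

test_that("mutateGenome realizes the requested divergence", {
    g <- makeGenome(100000, 0.34, seed = 1)
    expect_identical(
        as.character(genomeSequence(mutateGenome(g, 0, seed = 5))),
        as.character(genomeSequence(g)))
    m1 <- mutateGenome(g, 0.02, seed = 5)
    m2 <- mutateGenome(g, 0.02, seed = 5)
    expect_identical(as.character(genomeSequence(m1)),
        as.character(genomeSequence(m2)))
    d <- hammingFraction(as.character(genomeSequence(g)),
        as.character(genomeSequence(m1)))
    expect_gte(d, 0.0187)   # 3 binomial sd around 0.02 at 100 kbp
    expect_lte(d, 0.0213)
    expect_error(mutateGenome(g, 0.3, seed = 1), "divergence")
})

test_that("makeSagAssembly retains the right fraction as true substrings", {
    g <- makeGenome(50000, 0.34, seed = 3)
    full <- makeSagAssembly(g, completeness = 1, n_contigs = 1,
        family_loci = data.frame(family_id = "f1", start = 100,
            end = 200), seed = 1)
    expect_identical(as.character(contigs(full)[[1]]),
        as.character(genomeSequence(g)))
    expect_identical(detectedFamilies(full), "f1")

    half <- makeSagAssembly(g, completeness = 0.5, n_contigs = 10,
        seed = 2)
    expect_gte(assemblyLength(half) / 50000, 0.49)
    expect_lte(assemblyLength(half) / 50000, 0.51)
    gstr <- as.character(genomeSequence(g))
    offs <- contigOffsets(half)
    for (cn in names(contigs(half))) {
        w <- Biostrings::width(contigs(half)[cn])
        expect_identical(as.character(contigs(half)[[cn]]),
            substr(gstr, offs[[cn]] + 1L, offs[[cn]] + w))
    }
    # disjoint and in order
    ends <- offs + Biostrings::width(contigs(half))
    expect_true(all(offs[-1] >= ends[-length(ends)]))

    expect_error(makeSagAssembly(g, completeness = 1e-4,
        n_contigs = 10, seed = 1), "n_contigs")
})

test_that("detected-family fraction tracks completeness (Monte Carlo)", {
    g <- makeGenome(50000, 0.34, seed = 4)
    mstart <- round(seq(25, 49500, length.out = 94))
    loci <- data.frame(family_id = sprintf("SC%04d", 1:94),
        start = mstart, end = mstart + 1)
    fr <- vapply(1:100, function(i) {
        a <- makeSagAssembly(g, 0.5, n_contigs = 10,
            family_loci = loci, seed = i)
        length(detectedFamilies(a)) / 94
    }, 0)
    expect_gte(mean(fr), 0.45)
    expect_lte(mean(fr), 0.55)
})

test_that("makeMetagenome clean reads are exact substrings at zero divergence", {
    g <- makeGenome(20000, 0.34, seed = 1, genome_id = "gA")
    rs <- makeMetagenome(
        data.frame(genome_id = "gA", relative_abundance = 1,
            divergence = 0),
        list(gA = g), n_reads = 50, read_len_range = c(150, 300),
        seed = 2)
    expect_identical(length(rs), 50L)
    tt <- readTruth(rs)
    expect_true(all(tt$class == "clean"))
    gstr <- as.character(genomeSequence(g))
    for (i in seq_len(nrow(tt))) {
        src <- substr(gstr, tt$start[i] + 1L, tt$end[i])
        obs <- as.character(reads(rs)[[tt$read_id[i]]])
        if (tt$strand[i] == "-") src <- revcomp(src)
        expect_identical(obs, src)
    }
})

test_that("makeMetagenome junk classes and abundances follow their parameters", {
    g1 <- makeGenome(20000, 0.34, seed = 1, genome_id = "g1")
    g2 <- makeGenome(20000, 0.34, seed = 2, genome_id = "g2")
    rs <- makeMetagenome(
        data.frame(genome_id = c("g1", "g2"),
            relative_abundance = c(0.8, 0.2), divergence = 0),
        list(g1 = g1, g2 = g2), n_reads = 2000, seed = 3)
    tt <- readTruth(rs)
    n1 <- sum(tt$genome_id == "g1", na.rm = TRUE)
    n <- sum(tt$class == "clean")
    expect_lte(abs(n1 - 0.8 * n), 3 * sqrt(n * 0.8 * 0.2))

    rs2 <- makeMetagenome(
        data.frame(genome_id = "g1", relative_abundance = 1,
            divergence = 0),
        list(g1 = g1), n_reads = 1000,
        junk = c(0, 0, 0.1, 0), seed = 4)
    seqs <- as.character(reads(rs2))
    n_twin <- sum(vapply(seq_along(seqs), function(i)
        i > 1 && seqs[i] %in% seqs[seq_len(i - 1)], TRUE))
    expect_gte(n_twin, 100)

    expect_error(makeMetagenome(data.frame(), list(), 10, seed = 1),
        "non-empty")
    expect_error(makeMetagenome(
        data.frame(genome_id = "g1", relative_abundance = 0.5,
            divergence = 0), list(g1 = g1), 10, seed = 1), "sum to 1")
})

test_that("no clean read intersects a shielded interval", {
    g <- makeGenome(20000, 0.34, seed = 1, genome_id = "gA")
    shield <- data.frame(start = c(2000, 9000), end = c(3000, 10000))
    rs <- makeMetagenome(
        data.frame(genome_id = "gA", relative_abundance = 1,
            divergence = 0.02),
        list(gA = g), n_reads = 300, shielded = list(gA = shield),
        seed = 5)
    tt <- readTruth(rs)
    tt <- tt[tt$class == "clean", ]
    for (k in seq_len(nrow(shield))) {
        expect_false(any(tt$start < shield$end[k] &
            tt$end > shield$start[k]))
    }
})

test_that("makeOccurrenceMatrix plants single-copy structure", {
    m0 <- makeOccurrenceMatrix(100, n_single_copy = 94,
        n_accessory = 30, dropout = 0, dup_rate = 0, seed = 1)
    sc <- copyCounts(m0)[, sprintf("SC%04d", 1:94)]
    expect_true(all(sc == 1L))

    m5 <- makeOccurrenceMatrix(100, n_single_copy = 20,
        n_accessory = 0, dropout = 0.5, dup_rate = 0, seed = 2)
    cs <- deriveCscgs(m5)
    expect_length(cscgFamilies(cs), 0)

    expect_error(makeOccurrenceMatrix(5, 10, 0, seed = 1), ">= 10")
})

test_that("exactly-once marker survival matches the binomial tail oracle", {
    # P(a marker stays exactly-once in a genome) = 1 - dropout - dup
    n_seeds <- 100
    counts <- vapply(seq_len(n_seeds), function(i) {
        m <- makeOccurrenceMatrix(155, n_single_copy = 120,
            n_accessory = 0, dropout = 0.005, dup_rate = 0.005,
            seed = i)
        length(cscgFamilies(deriveCscgs(m)))
    }, 0)
    p_keep <- stats::pbinom(ceiling(0.98 * 155) - 1, 155, 0.99,
        lower.tail = FALSE)
    expected <- 120 * p_keep
    sd_mean <- sqrt(120 * p_keep * (1 - p_keep)) / sqrt(n_seeds)
    expect_lte(abs(mean(counts) - expected), 3 * sd_mean)
})

test_that("proteome triplet plants high-identity homologs and true uniques", {
    tri <- makeProteomeTriplet(1, 0, 0, 0, seed = 1)
    q <- as.character(tri$query[[1]])
    for (ref in list(tri$ref_a, tri$ref_b)) {
        expect_length(ref, 1)
        r <- as.character(ref[[1]])
        expect_identical(nchar(r), nchar(q))
        expect_gte(1 - hammingFraction(q, r), 0.70)
    }
    tri2 <- makeProteomeTriplet(0, 0, 0, 5, seed = 2)
    expect_length(tri2$ref_a, 0)
    expect_length(tri2$ref_b, 0)
    expect_identical(tri2$truth$category, rep("unique", 5))
    expect_error(makeProteomeTriplet(0, 0, 0, 0, seed = 1), "total")
})

test_that("SSU clouds are tight within and separated between", {
    cl <- makeSsuClouds(3, 4, seed = 1)
    expect_identical(nrow(cl), 12L)
    for (i in 1:3) {
        centre <- cl$seq[cl$cloud == i][1]
        within <- vapply(cl$seq[cl$cloud == i], hammingFraction, 0,
            a = centre)
        expect_true(all(within <= 0.01))
    }
    centres <- cl$seq[!duplicated(cl$cloud)]
    for (i in 1:2) for (j in (i + 1):3)
        expect_gte(hammingFraction(centres[i], centres[j]), 0.02)
})

test_that("generators are pure functions of their seed", {
    g <- makeGenome(20000, 0.34, seed = 9, genome_id = "gA")
    args <- list(
        data.frame(genome_id = "gA", relative_abundance = 1,
            divergence = 0.03),
        list(gA = g))
    r1 <- makeMetagenome(args[[1]], args[[2]], 100,
        junk = c(0.05, 0.05, 0.05, 0.05), seed = 11)
    r2 <- makeMetagenome(args[[1]], args[[2]], 100,
        junk = c(0.05, 0.05, 0.05, 0.05), seed = 11)
    expect_identical(as.character(reads(r1)), as.character(reads(r2)))
    expect_identical(readTruth(r1), readTruth(r2))
    a1 <- makeSagAssembly(g, 0.4, 5, seed = 3)
    a2 <- makeSagAssembly(g, 0.4, 5, seed = 3)
    expect_identical(as.character(contigs(a1)),
        as.character(contigs(a2)))
    t1 <- makeProteomeTriplet(2, 2, 2, 2, seed = 4)
    t2 <- makeProteomeTriplet(2, 2, 2, 2, seed = 4)
    expect_identical(as.character(t1$query), as.character(t2$query))
    # and the global RNG stream is left untouched
    set.seed(1); x1 <- runif(1)
    set.seed(1); invisible(makeGenome(1000, 0.5, seed = 2)); x2 <- runif(1)
    expect_identical(x1, x2)
})
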