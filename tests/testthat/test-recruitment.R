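test_that("localAlign finds exact substrings on both strands", {
    set.seed(30)
    contig <- randomSeq(1200)
    read <- substr(contig, 301, 550)
    h <- localAlign(read, contig)
    expect_identical(h$score, 250)
    expect_identical(h$identity, 1)
    expect_identical(h$aln_len, 250L)
    expect_identical(h$strand, "+")
    expect_identical(h$start, 300L)   # 0-based half-open
    expect_identical(h$end, 550L)

    hrc <- localAlign(revcomp(read), contig)
    expect_identical(hrc$score, 250)
    expect_identical(hrc$strand, "-")
    expect_identical(hrc$start, 300L)
})

test_that("localAlign identity counts substitutions over full columns", {
    set.seed(31)
    contig <- randomSeq(1000)
    read <- substr(contig, 201, 500)
    # 12 substitutions at interior positions, evenly spread
    read_mut <- plantSubs(read, round(seq(20, 280, length.out = 12)))
    h <- localAlign(read_mut, contig)
    expect_identical(h$aln_len, 300L)
    expect_equal(h$identity, 288 / 300)
    expect_identical(h$score, 288 - 12)
})

test_that("localAlign equals the exhaustive Gotoh oracle on short pairs", {
    set.seed(32)
    for (i in 1:250) {
        r <- randomSeq(sample(30:40, 1))
        s <- randomSeq(sample(30:40, 1))
        expect_identical(localAlign(r, s)$score,
            oracleLocalScoreBoth(r, s))
    }
})

test_that("recruitReads applies the length and identity thresholds", {
    set.seed(33)
    contig <- randomSeq(2000)
    ctg <- Biostrings::DNAStringSet(c(c1 = contig))
    base <- substr(contig, 501, 750)
    pass <- plantSubs(base, round(seq(15, 235, length.out = 10)))  # 0.96
    fail <- plantSubs(base, round(seq(15, 235, length.out = 15)))  # 0.94
    shorty <- substr(contig, 101, 290)                  # 190 cols < 200
    rds <- Biostrings::DNAStringSet(c(ok = pass, low = fail,
        short = shorty))
    hits <- recruitReads(rds, ctg, method = "full")
    expect_identical(S4Vectors::mcols(hits)$read_id, "ok")
    expect_equal(S4Vectors::mcols(hits)$identity, 240 / 250)
    hits2 <- recruitReads(rds, ctg, method = "seed")
    expect_identical(hitsTable(hits2), hitsTable(hits))
    expect_error(recruitReads(rds, Biostrings::DNAStringSet()),
        "empty assembly")
})

test_that("seed-and-extend agrees with whole-contig alignment", {
    g <- makeGenome(4000, 0.4, seed = 40, genome_id = "gB")
    rs <- makeMetagenome(
        data.frame(genome_id = "gB", relative_abundance = 1,
            divergence = 0.04),
        list(gB = g), n_reads = 50, read_len_range = c(220, 350),
        seed = 41)
    h_seed <- hitsTable(recruitReads(rs, g, method = "seed"))
    h_full <- hitsTable(recruitReads(rs, g, method = "full"))
    expect_identical(h_seed, h_full)
    # at most one hit per read
    expect_false(anyDuplicated(h_seed$read_id) > 0)
})

test_that("recruited fraction decreases with divergence", {
    g <- makeGenome(30000, 0.34, seed = 42, genome_id = "gA")
    frac <- vapply(c(0.02, 0.10), function(div) {
        rs <- makeMetagenome(
            data.frame(genome_id = "gA", relative_abundance = 1,
                divergence = div),
            list(gA = g), n_reads = 150,
            read_len_range = c(300, 300), seed = 43)
        length(recruitReads(rs, g)) / 150
    }, 0)
    expect_gte(frac[1], 0.95)
    expect_lte(frac[2], 0.05)
})

test_that("abundanceMatrix implements percent-per-Mbp normalization", {
    h <- data.frame(sample_id = rep("s1", 100), target_id = "t1")
    am1 <- abundanceMatrix(h, c(t1 = 1e6), c(s1 = 10000))
    expect_equal(SummarizedExperiment::assay(am1)["t1", "s1"], 1.0)
    am2 <- abundanceMatrix(h, c(t1 = 2e6), c(s1 = 10000))
    expect_equal(SummarizedExperiment::assay(am2)["t1", "s1"], 0.5)
    expect_error(abundanceMatrix(h, c(t1 = 1e6), c(s1 = 0)),
        "positive")
    expect_error(abundanceMatrix(h, c(other = 1e6), c(s1 = 100)),
        "unregistered")
    # zero-hit targets appear as zero rows
    am3 <- abundanceMatrix(h, c(t1 = 1e6, t2 = 1e6), c(s1 = 10000))
    expect_equal(SummarizedExperiment::assay(am3)["t2", "s1"], 0)
    expect_s4_class(am3, "AbundanceMatrix")
})

test_that("a 4:1 community recovers a 4:1 abundance ratio", {
    gA <- makeGenome(20000, 0.34, seed = 50, genome_id = "gA")
    gB <- makeGenome(20000, 0.34, seed = 51, genome_id = "gB")
    rs <- makeMetagenome(
        data.frame(genome_id = c("gA", "gB"),
            relative_abundance = c(0.8, 0.2), divergence = 0),
        list(gA = gA, gB = gB), n_reads = 400,
        read_len_range = c(250, 350), seed = 52)
    hits <- rbind(
        cbind(hitsTable(recruitReads(rs, gA)), sample_id = "s1"),
        cbind(hitsTable(recruitReads(rs, gB)), sample_id = "s1"))
    am <- abundanceMatrix(hits[, c("sample_id", "target_id")],
        c(gA = 20000, gB = 20000), c(s1 = 400))
    v <- SummarizedExperiment::assay(am)
    nA <- v["gA", "s1"] * 400 * 0.02 / 100   # back to counts
    sd3 <- 3 * sqrt(400 * 0.8 * 0.2)
    expect_lte(abs(nA - 320), sd3)
    expect_gt(v["gA", "s1"], v["gB", "s1"])
})

test_that("per-target abundance argmax recovers the depth structure", {
    gA <- makeGenome(15000, 0.34, seed = 60, genome_id = "gA")
    gB <- makeGenome(15000, 0.34, seed = 61, genome_id = "gB")
    genomes <- list(gA = gA, gB = gB)
    mk <- function(wA, sid, seed) makeMetagenome(
        data.frame(genome_id = c("gA", "gB"),
            relative_abundance = c(wA, 1 - wA), divergence = 0),
        genomes, 150, read_len_range = c(250, 350),
        sample_id = sid, seed = seed)
    s1 <- mk(0.85, "s1", 62)
    s2 <- mk(0.15, "s2", 63)
    rows <- list()
    for (rs in list(s1, s2)) for (g in genomes) {
        ht <- hitsTable(recruitReads(rs, g))
        if (nrow(ht)) rows[[paste(sampleId(rs), genomeId(g))]] <-
            cbind(ht, sample_id = sampleId(rs))
    }
    am <- abundanceMatrix(do.call(rbind, rows)[, c("sample_id",
        "target_id")], c(gA = 15000, gB = 15000),
        c(s1 = 150, s2 = 150))
    v <- SummarizedExperiment::assay(am)
    expect_identical(colnames(v)[apply(v, 1, which.max)][
        rownames(v) == "gA"], "s1")
    expect_identical(colnames(v)[apply(v, 1, which.max)][
        rownames(v) == "gB"], "s2")
})
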