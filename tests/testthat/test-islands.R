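grLoci <- function(starts, ends, ids, contig = "c1") {
    GenomicRanges::GRanges(contig,
        IRanges::IRanges(start = starts + 1L, end = ends),
        protein_id = ids)
}
grHits <- function(starts, ends, contig = "c1") {
    GenomicRanges::GRanges(contig,
        IRanges::IRanges(start = starts + 1L, end = ends))
}

test_that("callIslands applies the strict zero-recruitment rule", {
    loci <- grLoci(c(100, 1000), c(400, 1300), c("p1", "p2"))
    # one hit overlapping p1 by exactly 1 bp (hit [399, 600))
    hits <- grHits(399, 600)
    out <- callIslands(loci, hits, contigs = "c1")
    expect_identical(out$n_overlapping_recruits, c(1L, 0L))
    expect_identical(out$is_island, c(FALSE, TRUE))
    # adjacent but non-overlapping hit leaves the island call intact
    out2 <- callIslands(loci, grHits(400, 600), contigs = "c1")
    expect_identical(out2$is_island, c(TRUE, TRUE))
    expect_error(callIslands(loci, hits, contigs = "other"),
        "unknown contig")
})

test_that("overlap counting agrees with a per-base scan", {
    set.seed(80)
    for (rep in 1:5) {
        ls <- sample(0:900, 12)
        le <- ls + sample(30:100, 12, replace = TRUE)
        hs <- sample(0:950, 30, replace = TRUE)
        he <- hs + sample(20:80, 30, replace = TRUE)
        loci <- grLoci(ls, le, sprintf("p%02d", 1:12))
        hits <- grHits(hs, he)
        out <- callIslands(loci, hits, contigs = "c1")
        hdf <- data.frame(contig = "c1", start = hs, end = he)
        for (i in 1:12) {
            expect_identical(out$n_overlapping_recruits[i],
                oracleOverlapCount(ls[i], le[i], "c1", hdf))
        }
    }
})

test_that("adding a hit can only destroy island status, never create it", {
    set.seed(81)
    ls <- sample(0:900, 10)
    loci <- grLoci(ls, ls + 50, sprintf("p%02d", 1:10))
    h1s <- sample(0:950, 15, replace = TRUE)
    hits1 <- grHits(h1s, h1s + 40)
    h2s <- sample(0:950, 5, replace = TRUE)
    extra <- grHits(h2s, h2s + 40)
    a <- callIslands(loci, hits1, contigs = "c1")
    b <- callIslands(loci, c(hits1, extra), contigs = "c1")
    expect_true(all(b$is_island <= a$is_island))
})

test_that("island calls match generator shielding truth at high coverage", {
    g <- makeGenome(12000, 0.34, seed = 82, genome_id = "gA")
    w <- 600L
    starts <- seq(0L, 11 * 1000L, by = 1000L) + 50L
    ploci <- data.frame(family_id = sprintf("p%02d", 1:12),
        start = starts, end = starts + w)
    island_idx <- c(2L, 6L, 11L)
    # shields extend 10 bp past the locus so boundary-adjacent reads
    # cannot leak alignment columns into an island locus
    shield <- data.frame(start = ploci$start[island_idx] - 10L,
        end = ploci$end[island_idx] + 10L)
    asm <- makeSagAssembly(g, 1, n_contigs = 1, family_loci = ploci,
        seed = 83, sag_id = "sagA")
    rs <- makeMetagenome(
        data.frame(genome_id = "gA", relative_abundance = 1,
            divergence = 0),
        list(gA = g), n_reads = 800, read_len_range = c(300, 350),
        shielded = list(gA = shield), seed = 84)   # ~21x coverage
    hits <- recruitReads(rs, asm)
    loci <- codingLoci(asm)
    S4Vectors::mcols(loci)$protein_id <-
        S4Vectors::mcols(loci)$family_id
    out <- callIslands(loci, hits, contigs = names(contigs(asm)))
    truth <- out$protein_id %in% ploci$family_id[island_idx]
    expect_identical(out$is_island, truth)
})

test_that("cogEnrichment reproduces the exact hypergeometric tail", {
    ids <- sprintf("p%04d", 1:1000)
    cats <- setNames(rep(LETTERS[1:10], each = 100), ids)
    calls <- data.frame(protein_id = ids,
        n_overlapping_recruits = rep(c(0L, 3L), c(20, 980)),
        is_island = rep(c(TRUE, FALSE), c(20, 980)))
    cats[calls$protein_id[calls$is_island]] <- "J"  # all 20 in one cat
    cats[ids[21:120]] <- "J"                        # background 120 Js
    # recount: category J has 120 members, islands all 20 of them
    res <- cogEnrichment(calls, cats)
    pj <- res$p_value[res$category == "J"]
    oracle <- exp(lchoose(120, 20) - lchoose(1000, 20))
    expect_equal(pj, oracle, tolerance = 1e-10)
    expect_true(res$enriched[res$category == "J"])
})

test_that("proportional island composition is never called enriched", {
    ids <- sprintf("p%04d", 1:500)
    cats <- setNames(rep(LETTERS[1:10], each = 50), ids)
    is_isl <- rep(FALSE, 500)
    is_isl[seq(1, 500, by = 25)] <- TRUE   # 2 per category
    calls <- data.frame(protein_id = ids,
        n_overlapping_recruits = ifelse(is_isl, 0L, 2L),
        is_island = is_isl)
    res <- cogEnrichment(calls, cats)
    expect_false(any(res$enriched))
})

test_that("degenerate single-category input yields p = 1", {
    ids <- sprintf("p%02d", 1:30)
    cats <- setNames(rep("V", 30), ids)
    calls <- data.frame(protein_id = ids,
        n_overlapping_recruits = rep(c(0L, 1L), c(5, 25)),
        is_island = rep(c(TRUE, FALSE), c(5, 25)))
    res <- cogEnrichment(calls, cats)
    expect_equal(res$p_value, 1)
    calls$is_island[] <- FALSE
    expect_warning(res0 <- cogEnrichment(calls, cats), "empty")
    expect_identical(nrow(res0), 0L)
})
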