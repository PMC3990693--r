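test_that("pairwiseIdentity handles substitutions and terminal gaps", {
    set.seed(90)
    a <- randomSeq(1000)
    expect_equal(pairwiseIdentity(a, a), 1)
    b <- plantSubs(a, round(seq(50, 950, length.out = 10)))
    expect_equal(pairwiseIdentity(a, b), 0.99)
    expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
    # a partial-length amplicon matches over the overlap only
    expect_equal(pairwiseIdentity(substr(a, 201, 800), a), 1)
    expect_error(pairwiseIdentity("ACGT", a), "at least")
})

test_that("internal gaps count as mismatching columns", {
    set.seed(91)
    a <- randomSeq(600)
    # delete 6 interior bases: best alignment has 6 internal gap columns
    b <- paste0(substr(a, 1, 300), substr(a, 307, 600))
    id <- pairwiseIdentity(a, b)
    expect_equal(id, 594 / 600)
})

test_that("pairwiseIdentity score agrees with the overlap DP oracle", {
    set.seed(92)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
        mismatch = -1, baseOnly = TRUE)
    for (i in 1:25) {
        a <- randomSeq(sample(30:50, 1))
        b <- randomSeq(sample(30:50, 1))
        sc <- Biostrings::score(Biostrings::pairwiseAlignment(a, b,
            type = "overlap", substitutionMatrix = mat,
            gapOpening = 0, gapExtension = 2))
        expect_equal(sc, oracleOverlapScore(a, b))
    }
    # and identity equals hamming identity for equal-length
    # substitution-only pairs
    for (i in 1:10) {
        a <- randomSeq(300)
        b <- plantSubs(a, sample(20:280, 6))
        expect_equal(pairwiseIdentity(a, b),
            1 - hammingFraction(a, b))
    }
})

test_that("identical sequences collapse to one phylotype with site counts", {
    s <- randomSeq(800)
    d <- data.frame(id = c("x1", "x2", "x3"), seq = s,
        site = c("A", "A", "B"))
    res <- clusterPhylotypes(d)
    expect_identical(nrow(res$phylotypes), 1L)
    expect_identical(res$phylotypes$n_members, 3L)
    expect_identical(res$site_counts[1, c("A", "B")],
        c(A = 2L, B = 1L))
    # 95% identity pair splits at the 99% threshold
    d2 <- data.frame(id = c("y1", "y2"),
        seq = c(s, plantSubs(s, seq(10, 790, by = 20))),
        site = "A")
    expect_identical(nrow(clusterPhylotypes(d2)$phylotypes), 2L)
})

test_that("well-separated clouds are recovered exactly", {
    cl <- makeSsuClouds(4, 5, seed = 93)
    res <- clusterPhylotypes(cl[, c("id", "seq", "site")])
    expect_identical(nrow(res$phylotypes), 4L)
    got <- split(res$members$id, res$members$phylotype_id)
    want <- split(cl$id, cl$cloud)
    expect_setequal(
        unname(vapply(got, function(x) paste(sort(x), collapse = ","),
            "")),
        unname(vapply(want, function(x) paste(sort(x), collapse = ","),
            "")))
})

test_that("clustering is a partition under input permutations", {
    cl <- makeSsuClouds(3, 4, seed = 94)
    set.seed(95)
    for (i in 1:20) {
        perm <- cl[sample(nrow(cl)), c("id", "seq", "site")]
        res <- clusterPhylotypes(perm)
        expect_setequal(res$members$id, cl$id)
        expect_false(anyDuplicated(res$members$id) > 0)
        expect_identical(nrow(res$phylotypes), 3L)
        expect_identical(sum(res$phylotypes$n_members), nrow(cl))
    }
})

test_that("summarizeScreen reproduces per-site and pooled percentages", {
    det <- data.frame(
        sag_id = sprintf("s%03d", 1:119),
        site = rep(c("South Atlantic", "North Pacific"), c(67, 52)),
        depth_m = rep(c(800, 770), c(67, 52)),
        amoA = c(rep(TRUE, 40), rep(FALSE, 27),
                 rep(TRUE, 42), rep(FALSE, 10)),
        nirK = c(rep(TRUE, 32), rep(FALSE, 35),
                 rep(TRUE, 32), rep(FALSE, 20)))
    out <- summarizeScreen(det)
    sa <- out[out$site == "South Atlantic", ]
    np <- out[out$site == "North Pacific", ]
    tot <- out[out$site == "Total", ]
    expect_identical(sa$n_sags, 67L)
    expect_identical(c(sa$amoA_n, sa$amoA_pct), c(40L, 60L))
    expect_identical(c(sa$nirK_n, sa$nirK_pct), c(32L, 48L))
    expect_identical(c(np$amoA_n, np$amoA_pct), c(42L, 81L))
    expect_identical(c(np$nirK_n, np$nirK_pct), c(32L, 62L))
    expect_identical(c(tot$n_sags, tot$amoA_n, tot$amoA_pct),
        c(119L, 82L, 69L))
    expect_identical(c(tot$nirK_n, tot$nirK_pct), c(64L, 54L))
})

test_that("percentages round half away from zero", {
    det <- data.frame(sag_id = sprintf("s%d", 1:8), site = "X",
        depth_m = 0, g = c(TRUE, rep(FALSE, 7)))
    out <- summarizeScreen(det)
    expect_identical(out$g_pct[out$site == "X"], 13L)  # 12.5 -> 13
    expect_error(summarizeScreen(data.frame(sag_id = "a", site = "X",
        depth_m = 0, g = 1)), "logical")
})
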