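# Independent brute-force oracles used to validate the package's
# primitives. These deliberately share no code with the implementation:
# alignments are scored by a plain R Gotoh dynamic program, entropy by
# an explicit trimer count, marker derivation by a per-family loop.

revcomp <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
        collapse = ""))
}

hammingFraction <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    stopifnot(length(av) == length(bv))
    mean(av != bv)
}

# Gotoh local alignment score with affine gaps: a gap of length k costs
# open + k * ext. `sub` is either a list(match=, mismatch=) or a
# substitution matrix indexed by characters.
oracleLocalScore <- function(a, b, open = 2, ext = 1,
                             sub = list(match = 1, mismatch = -1)) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A)
    m <- length(B)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)
    Ix <- matrix(NEG, n + 1, m + 1)
    Iy <- matrix(NEG, n + 1, m + 1)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (is.matrix(sub)) sub[A[i], B[j]] else
                if (A[i] == B[j]) sub$match else sub$mismatch
            Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                Ix[i, j + 1] - ext)
            Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                Iy[i + 1, j] - ext)
            M[i + 1, j + 1] <- max(0,
                max(M[i, j], Ix[i, j], Iy[i, j]) + s)
            if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
        }
    }
    best
}

# strand-aware version matching localAlign()'s search space
oracleLocalScoreBoth <- function(read, contig, ...) {
    max(oracleLocalScore(read, contig, ...),
        oracleLocalScore(revcomp(read), contig, ...))
}

# ends-free global (overlap) alignment score with linear gap cost
oracleOverlapScore <- function(a, b, match = 1, mismatch = -1,
                               gap = 2) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A)
    m <- length(B)
    H <- matrix(0, n + 1, m + 1)
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (A[i] == B[j]) match else mismatch
            H[i + 1, j + 1] <- max(H[i, j] + s, H[i, j + 1] - gap,
                H[i + 1, j] - gap)
        }
    }
    max(H[n + 1, ], H[, m + 1])
}

# explicit overlapping-trimer entropy on the 0-100 scale
oracleEntropy <- function(s) {
    L <- nchar(s)
    counts <- integer(0)
    for (i in seq_len(L - 2)) {
        tri <- substr(s, i, i + 2)
        counts[tri] <- if (is.na(counts[tri])) 1L else counts[tri] + 1L
    }
    p <- counts / sum(counts)
    H <- -sum(p * log2(p))
    100 * H / log2(min(L - 2, 64))
}

# per-family loop for CSCG derivation
oracleCscgs <- function(copies, threshold = 0.98) {
    need <- ceiling(threshold * nrow(copies))
    out <- character(0)
    for (fam in colnames(copies)) {
        n_once <- 0L
        for (g in rownames(copies)) {
            if (copies[g, fam] == 1L) n_once <- n_once + 1L
        }
        if (n_once >= need) out <- c(out, fam)
    }
    out
}

# per-base scan: does any hit interval share >= 1 bp with the locus?
oracleOverlapCount <- function(locus_start, locus_end, locus_contig,
                               hits_df) {
    n <- 0L
    for (i in seq_len(nrow(hits_df))) {
        if (hits_df$contig[i] != locus_contig) next
        shared <- FALSE
        for (p in seq(locus_start, locus_end - 1L)) {
            if (p >= hits_df$start[i] && p < hits_df$end[i]) {
                shared <- TRUE
                break
            }
        }
        if (shared) n <- n + 1L
    }
    n
}

# cyclic de Bruijn sequence B(4, 3) via the standard Lyndon-word
# concatenation; every trimer occurs exactly once per cycle
deBruijn43 <- function() {
    k <- 4L; n <- 3L
    alphabet <- c("A", "C", "G", "T")
    a <- integer(k * n)
    seqv <- integer(0)
    db <- function(t, p) {
        if (t > n) {
            if (n %% p == 0L) seqv <<- c(seqv, a[2:(p + 1)])
        } else {
            a[t + 1L] <<- a[t - p + 1L]
            db(t + 1L, p)
            j0 <- a[t - p + 1L] + 1L
            if (j0 <= k - 1L) {
                for (j in seq.int(j0, k - 1L)) {
                    a[t + 1L] <<- j
                    db(t + 1L, t)
                }
            }
        }
    }
    db(1L, 1L)
    paste(alphabet[seqv + 1L], collapse = "")
}

# a random A/C/G/T string (for oracle-vs-implementation sweeps)
randomSeq <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# plant substitutions at given 1-based positions, cycling each base to
# the next letter so the change is guaranteed
plantSubs <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    nxt <- c(A = "C", C = "G", G = "T", T = "A")
    ch[pos] <- nxt[ch[pos]]
    paste(ch, collapse = "")
}
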