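# Seeded randomness helpers. Every generator in the package is a pure
# function of its arguments including `seed`: randomness runs inside
# withr::with_seed so the caller's RNG state is never touched.

#' @importFrom withr with_seed
withSeed <- function(seed, code) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
}

#' Derive a per-stage seed from a global seed
#'
#' Fans a single pipeline seed out to stage-local seeds by stable hashing
#' of the stage name, so toggling stages on or off never changes the
#' random stream another stage sees.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @examples
#' stageSeed(1, "simulate")
#' stageSeed(1, "recruit")
#' @export
stageSeed <- function(seed, stage) {
    stopifnot(length(stage) == 1L, is.character(stage))
    h <- 0
    for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
    as.integer((as.numeric(seed) %% 2147483647 * 131 + h) %% 2147483647)
}

# uniform random DNA with P(G) + P(C) = gc
randomDna <- function(n, gc = 0.5) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

randomProtein <- function(n) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
        replace = TRUE), collapse = "")
}

reverseComplement1 <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# uniform integer draw from [lo, hi], safe when lo == hi (unlike
# sample(lo:hi, ...) which falls into sample.int when the vector has
# length 1)
sampleRange <- function(lo, hi, n = 1L) {
    lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}
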