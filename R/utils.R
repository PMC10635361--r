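# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, code) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    force(code)
}

# Draw integers uniformly from an inclusive range given as c(min, max) or a
# single fixed value.
sampleRange <- function(n, range, what = "range") {
    if (length(range) == 1L) range <- c(range, range)
    if (length(range) != 2L || any(range <= 0) || range[2] < range[1])
        stop(what, " must be a positive value or increasing pair")
    if (range[1] == range[2]) rep(as.integer(range[1]), n)
    else as.integer(range[1]) +
        as.integer(floor(runif(n) * (range[2] - range[1] + 1)))
}

# DESeq-style median-of-ratios size factors over the rows of a count matrix.
medianOfRatios <- function(counts) {
    logGeo <- rowMeans(log(counts))
    use <- is.finite(logGeo)
    if (!any(use))
        return(setNames(rep(1, ncol(counts)), colnames(counts)))
    sf <- apply(counts[use, , drop = FALSE], 2L, function(col)
        exp(median(log(col) - logGeo[use], na.rm = TRUE)))
    sf[!is.finite(sf) | sf <= 0] <- 1
    sf
}
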