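# Pairwise sharing of significant effects between analyses.
#
# Two effects are shared when they have the same sign and are within a
# factor of 0.5 of each other (the larger magnitude times 0.5 is at most
# the smaller, boundary inclusive). The denominator of a pair is the set of
# features significant (q < 0.05) in at least one of the two analyses.
# Sharing is computed on the estimated effects directly; no empirical-Bayes
# shrinkage of the effect matrix is performed.

#' Aggregate exon-level splicing results to gene level
#'
#' Each gene is represented by its most significant exon (minimum p-value
#' among tested exons; ties broken by the lexicographically smallest exon
#' id), whose effect, Z, p and q are carried over.
#'
#' @param res a per-exon result `DataFrame` from [testExonUsage()].
#' @return A `DataFrame` with one row per gene that has at least one tested
#'   exon: `gene_id`, `exon_id` (the representative exon), `log2fc`, `z`,
#'   `pvalue`, `qvalue`, `significant`.
#' @export
aggregateToGene <- function(res) {
    tested <- res[res$tested & !is.na(res$pvalue), , drop = FALSE]
    if (nrow(tested) == 0L)
        return(DataFrame(gene_id = character(0), exon_id = character(0),
                         log2fc = numeric(0), z = numeric(0),
                         pvalue = numeric(0), qvalue = numeric(0),
                         significant = logical(0)))
    o <- order(tested$gene_id, tested$pvalue, tested$exon_id)
    tested <- tested[o, , drop = FALSE]
    keep <- !duplicated(tested$gene_id)
    out <- tested[keep, c("gene_id", "exon_id", "log2fc", "z",
                          "pvalue", "qvalue", "significant"),
                  drop = FALSE]
    metadata(out) <- metadata(res)
    rownames(out) <- out$gene_id
    out
}

#' Build an EffectMatrix from per-analysis result tables
#'
#' Aligns a list of result tables (from [testExonUsage()],
#' [aggregateToGene()] or [testGeneExpression()]) on their feature ids and
#' collects effects, Z scores and significance flags. Features missing from
#' an analysis get NA effects and are never significant there.
#'
#' @param results named list of result `DataFrame`s; names become the
#'   analysis labels.
#' @param idColumn feature id column; by default `gene_id` if present in
#'   all tables, else `exon_id`.
#' @return An [EffectMatrix-class].
#' @export
collectEffects <- function(results, idColumn = NULL) {
    stopifnot(is.list(results), length(results) >= 1L,
              !is.null(names(results)))
    if (is.null(idColumn))
        idColumn <- if (all(vapply(results, function(r)
            "gene_id" %in% colnames(r), logical(1)))) "gene_id"
            else "exon_id"
    ids <- sort(unique(unlist(lapply(results, function(r)
        as.character(r[[idColumn]])))))
    k <- length(results)
    eff <- z <- matrix(NA_real_, length(ids), k,
                       dimnames = list(ids, names(results)))
    sig <- matrix(FALSE, length(ids), k,
                  dimnames = list(ids, names(results)))
    for (j in seq_len(k)) {
        r <- results[[j]]
        i <- match(as.character(r[[idColumn]]), ids)
        eff[i, j] <- r$log2fc
        if ("z" %in% colnames(r)) z[i, j] <- r$z
        sig[i, j] <- r$significant %in% TRUE
    }
    effectMatrix(eff, sig, z)
}

#' Pairwise sharing fraction between two analyses
#'
#' Among features significant (q < 0.05) in at least one of the two
#' analyses, the fraction whose effects have the same sign and magnitudes
#' within a factor of 0.5 of each other (inclusive). An effect of exactly
#' zero shares sign with nothing. Features with an NA effect in either
#' analysis are excluded from the denominator.
#'
#' @param em an [EffectMatrix-class].
#' @param pair character vector of two analysis labels (self-pairs
#'   allowed).
#' @param factor sharing factor in (0, 1]; default 0.5.
#' @return A list with `fraction` (NA if the denominator is empty) and `n`
#'   (the denominator size).
#' @export
pairwiseSharing <- function(em, pair, factor = 0.5) {
    stopifnot(is(em, "EffectMatrix"), length(pair) == 2L)
    if (!all(pair %in% colnames(em@effects)))
        stop("unknown analysis label: ",
             paste(setdiff(pair, colnames(em@effects)), collapse = ", "))
    if (factor <= 0 || factor > 1)
        stop("factor must lie in (0, 1]")
    a <- em@effects[, pair[1L]]
    b <- em@effects[, pair[2L]]
    sig <- (em@significant[, pair[1L]] | em@significant[, pair[2L]]) &
        !is.na(a) & !is.na(b)
    n <- sum(sig)
    if (n == 0L)
        return(list(fraction = NA_real_, n = 0L))
    a <- a[sig]; b <- b[sig]
    sameSign <- sign(a) == sign(b) & a != 0 & b != 0
    within <- pmax(abs(a), abs(b)) * factor <= pmin(abs(a), abs(b))
    list(fraction = sum(sameSign & within) / n, n = n)
}

#' Sharing matrix over all analysis pairs
#'
#' Applies [pairwiseSharing()] to every pair of analyses in the effect
#' matrix; symmetric by construction.
#'
#' @param em an [EffectMatrix-class] with >= 2 analyses (self-comparison
#'   diagonals are included).
#' @param factor sharing factor; default 0.5.
#' @return A [SharingMatrix-class].
#' @export
sharingMatrix <- function(em, factor = 0.5) {
    labs <- colnames(em@effects)
    k <- length(labs)
    s <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
    n <- matrix(0L, k, k, dimnames = list(labs, labs))
    for (i in seq_len(k))
        for (j in i:k) {
            ps <- pairwiseSharing(em, c(labs[i], labs[j]), factor)
            s[i, j] <- s[j, i] <- ps$fraction
            n[i, j] <- n[j, i] <- ps$n
        }
    new("SharingMatrix", sharing = s, n = n)
}
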