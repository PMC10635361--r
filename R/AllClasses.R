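#' Study design for a differentiation time course
#'
#' Describes the sample layout simulated and analysed by the package: a set
#' of cohorts, an ordered differentiation time course, a number of subjects
#' per cohort, and a number of technical sequencing runs per library.
#'
#' @slot cohorts character vector of cohort labels.
#' @slot timepoints ordered character vector of time-point labels.
#' @slot subjectsPerCohort integer, subjects sampled in each cohort.
#' @slot runsPerSample integer, technical sequencing runs per
#'   subject-by-time-point library.
#'
#' @export
setClass("StudyDesign",
    representation(
        cohorts = "character",
        timepoints = "character",
        subjectsPerCohort = "integer",
        runsPerSample = "integer"
    )
)

setValidity("StudyDesign", function(object) {
    msg <- NULL
    if (length(object@timepoints) < 2L)
        msg <- c(msg, "need at least 2 timepoints")
    if (length(object@cohorts) < 1L)
        msg <- c(msg, "need at least 1 cohort")
    if (object@subjectsPerCohort < 1L)
        msg <- c(msg, "need at least 1 subject per cohort")
    if (object@runsPerSample < 1L)
        msg <- c(msg, "need at least 1 run per sample")
    if (anyDuplicated(object@cohorts) || anyDuplicated(object@timepoints))
        msg <- c(msg, "cohort and timepoint labels must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a StudyDesign
#'
#' @param cohorts character vector of cohort labels.
#' @param timepoints ordered character vector of time-point labels; the
#'   order defines the comparisons (consecutive pairs) tested downstream.
#' @param subjectsPerCohort number of subjects per cohort.
#' @param runsPerSample number of technical sequencing runs per library.
#'
#' @return A [StudyDesign-class] object. The defaults reproduce the layout
#'   analysed throughout the package: three cohorts (lean, obese, obese with
#'   type-2 diabetes), three time points (confluence, day 3, day 15 of
#'   differentiation), three subjects per cohort and two sequencing runs.
#'
#' @examples
#' studyDesign()
#' @export
studyDesign <- function(cohorts = c("lean", "obese", "obese_T2D"),
                        timepoints = c("confluence", "day3", "day15"),
                        subjectsPerCohort = 3L,
                        runsPerSample = 2L) {
    new("StudyDesign",
        cohorts = as.character(cohorts),
        timepoints = as.character(timepoints),
        subjectsPerCohort = as.integer(subjectsPerCohort),
        runsPerSample = as.integer(runsPerSample))
}

setMethod("show", "StudyDesign", function(object) {
    cat("StudyDesign:",
        length(object@cohorts), "cohorts x",
        length(object@timepoints), "timepoints x",
        object@subjectsPerCohort, "subjects x",
        object@runsPerSample, "runs\n")
    cat("  cohorts:   ", paste(object@cohorts, collapse = ", "), "\n")
    cat("  timepoints:", paste(object@timepoints, collapse = " -> "), "\n")
})

#' Exon-level count container
#'
#' A \linkS4class{RangedSummarizedExperiment} holding integer exon counts
#' (exons x samples), with exons grouped into genes via
#' \code{rowData()$gene_id} / \code{rowData()$exon_id} and the sample layout
#' (cohort, timepoint, subject, run) in \code{colData()}.
#'
#' @export
setClass("ExonCountSet",
    contains = "RangedSummarizedExperiment")

setValidity("ExonCountSet", function(object) {
    msg <- NULL
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(cts < 0) || any(cts != round(cts)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    rd <- rowData(object)
    if (!all(c("gene_id", "exon_id") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain gene_id and exon_id")
    else if (anyDuplicated(rd$exon_id))
        msg <- c(msg, "exon_id must be unique")
    cd <- colData(object)
    need <- c("cohort", "timepoint", "subject", "run")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must contain",
                            paste(need, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Construct an ExonCountSet
#'
#' @param counts integer matrix, exons x samples.
#' @param rowRanges `GRanges` of exon coordinates carrying `gene_id`,
#'   `exon_id` (and optionally `exon_rank`) metadata columns, as produced by
#'   [simulateGeneModels()].
#' @param colData `DataFrame`/`data.frame` with one row per sample and
#'   columns `cohort`, `timepoint`, `subject`, `run`.
#'
#' @return An [ExonCountSet-class].
#' @export
ExonCountSet <- function(counts, rowRanges, colData) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = rowRanges,
        colData = DataFrame(colData))
    rownames(se) <- rowData(se)$exon_id
    new("ExonCountSet", se)
}

#' @describeIn ExonCountSet-class exon identifiers (one per row).
#' @param object an `ExonCountSet`.
#' @export
setGeneric("exonIds", function(object) standardGeneric("exonIds"))

#' @export
setMethod("exonIds", "ExonCountSet",
    function(object) as.character(rowData(object)$exon_id))

#' @describeIn ExonCountSet-class gene identifier of each exon row.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @export
setMethod("geneIds", "ExonCountSet",
    function(object) as.character(rowData(object)$gene_id))

setMethod("show", "ExonCountSet", function(object) {
    cat("ExonCountSet:", nrow(object), "exons in",
        length(unique(geneIds(object))), "genes,",
        ncol(object), "samples\n")
    cd <- colData(object)
    cat("  cohorts:   ", paste(unique(cd$cohort), collapse = ", "), "\n")
    cat("  timepoints:", paste(unique(cd$timepoint), collapse = ", "), "\n")
    if ("testable" %in% colnames(rowData(object)))
        cat("  testable exons:", sum(rowData(object)$testable), "\n")
})

#' Effect estimates across analyses
#'
#' Features (exons or genes) by analyses matrix of effect estimates, with
#' matching Z scores and per-analysis significance flags, the input to the
#' pairwise-sharing computation.
#'
#' @slot effects numeric matrix, features x analyses.
#' @slot z numeric matrix of Z scores (same shape), possibly all-NA.
#' @slot significant logical matrix of q < 0.05 flags (same shape).
#'
#' @export
setClass("EffectMatrix",
    representation(
        effects = "matrix",
        z = "matrix",
        significant = "matrix"
    )
)

setValidity("EffectMatrix", function(object) {
    msg <- NULL
    d <- dim(object@effects)
    if (!identical(dim(object@significant), d))
        msg <- c(msg, "significant must match effects in shape")
    if (!identical(dim(object@z), d))
        msg <- c(msg, "z must match effects in shape")
    if (is.null(colnames(object@effects)))
        msg <- c(msg, "analyses (columns) must be named")
    if (is.null(msg)) TRUE else msg
})

#' Construct an EffectMatrix
#'
#' @param effects numeric matrix (features x analyses) of effect estimates
#'   (e.g. log2 fold changes), with named columns.
#' @param significant logical matrix of the same shape flagging effects
#'   significant (q < 0.05) in each analysis.
#' @param z optional numeric matrix of Z scores; defaults to NA.
#'
#' @return An [EffectMatrix-class].
#' @export
effectMatrix <- function(effects, significant, z = NULL) {
    effects <- as.matrix(effects)
    significant <- as.matrix(significant)
    significant[is.na(significant)] <- FALSE
    if (is.null(z))
        z <- matrix(NA_real_, nrow(effects), ncol(effects),
                    dimnames = dimnames(effects))
    new("EffectMatrix", effects = effects, z = as.matrix(z),
        significant = significant)
}

setMethod("show", "EffectMatrix", function(object) {
    cat("EffectMatrix:", nrow(object@effects), "features x",
        ncol(object@effects), "analyses\n")
    cat("  analyses:", paste(colnames(object@effects), collapse = ", "), "\n")
    cat("  significant effects per analysis:",
        paste(colSums(object@significant, na.rm = TRUE), collapse = ", "),
        "\n")
})

#' Pairwise sharing of significant effects
#'
#' Symmetric matrix of sharing fractions between analyses, with the number
#' of effects entering each pair's denominator. An entry is NA when neither
#' analysis of the pair has a significant effect.
#'
#' @slot sharing numeric symmetric matrix of fractions in [0, 1] (or NA).
#' @slot n integer matrix of denominator sizes.
#'
#' @export
setClass("SharingMatrix",
    representation(sharing = "matrix", n = "matrix"))

setValidity("SharingMatrix", function(object) {
    msg <- NULL
    s <- object@sharing
    if (!isTRUE(all.equal(s, t(s))) &&
        !identical(is.na(s), is.na(t(s))))
        msg <- c(msg, "sharing matrix must be symmetric")
    ok <- s[!is.na(s)]
    if (length(ok) && (any(ok < 0) || any(ok > 1)))
        msg <- c(msg, "sharing fractions must lie in [0, 1]")
    if (!identical(dim(object@n), dim(s)))
        msg <- c(msg, "n must match sharing in shape")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SharingMatrix", function(object) {
    cat("SharingMatrix over", ncol(object@sharing), "analyses\n")
    print(round(object@sharing, 3))
})

#' @describeIn SharingMatrix-class the sharing fractions as a plain matrix.
#' @param object a `SharingMatrix`.
#' @export
setGeneric("sharingFractions",
    function(object) standardGeneric("sharingFractions"))

#' @export
setMethod("sharingFractions", "SharingMatrix",
    function(object) object@sharing)

#' Fuzzy c-means cluster model
#'
#' Result of fuzzy c-means clustering of standardized exon-usage
#' trajectories: centroids, soft membership matrix, the fuzzifier and the
#' objective-function trace of the best restart.
#'
#' @slot centroids k x timepoints numeric matrix.
#' @slot membership exons x k numeric matrix; rows sum to 1.
#' @slot m fuzzifier (> 1).
#' @slot objective objective value after each iteration (non-increasing).
#' @slot seed integer seed used for initialization.
#'
#' @export
setClass("FuzzyClusterModel",
    representation(
        centroids = "matrix",
        membership = "matrix",
        m = "numeric",
        objective = "numeric",
        seed = "integer"
    )
)

setValidity("FuzzyClusterModel", function(object) {
    msg <- NULL
    u <- object@membership
    if (any(u < -1e-8) || any(u > 1 + 1e-8))
        msg <- c(msg, "memberships must lie in [0, 1]")
    if (any(abs(rowSums(u) - 1) > 1e-8))
        msg <- c(msg, "membership rows must sum to 1")
    if (ncol(u) != nrow(object@centroids))
        msg <- c(msg, "membership columns must match number of centroids")
    if (object@m <= 1)
        msg <- c(msg, "fuzzifier m must be > 1")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "FuzzyClusterModel", function(object) {
    cat("FuzzyClusterModel: k =", nrow(object@centroids),
        ", m =", object@m,
        ",", nrow(object@membership), "trajectories\n")
    cat("  final objective:",
        format(object@objective[length(object@objective)]), "after",
        length(object@objective), "iterations\n")
})

#' @describeIn FuzzyClusterModel-class cluster centroids (k x timepoints).
#' @param object a `FuzzyClusterModel`.
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @export
setMethod("centroids", "FuzzyClusterModel", function(object) object@centroids)

#' @describeIn FuzzyClusterModel-class soft membership matrix (exons x k).
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))

#' @export
setMethod("memberships", "FuzzyClusterModel",
    function(object) object@membership)

#' Flanking introns of exons within gene models
#'
#' The set of intronic intervals of a gene annotation together with the
#' mapping from each exon to its (up to two) flanking introns. Introns
#' shared by adjacent exons are stored once and identified by id;
#' deduplication when counting is by identical coordinates.
#'
#' @slot introns `GRanges` of intron intervals, named by intron id.
#' @slot flanks named `CharacterList`: exon id -> intron ids (0-2 each).
#'
#' @export
setClass("IntronFlankSet",
    representation(introns = "GRanges", flanks = "CharacterList"))

setMethod("show", "IntronFlankSet", function(object) {
    cat("IntronFlankSet:", length(object@introns), "introns flanking",
        length(object@flanks), "exons\n")
})

#' Permutation enrichment result
#'
#' Observed number of flanking introns overlapping at least one SNP, the
#' permutation null distribution from matched random exon sets, the
#' empirical percentile of the observed value and the enrichment call.
#'
#' @slot observed integer, introns of the test set overlapping >= 1 SNP.
#' @slot nullCounts integer vector of length `nPerm`.
#' @slot percentile fraction of null counts strictly below observed.
#' @slot call one of "enriched", "depleted", "ns".
#' @slot nPerm number of control sets.
#' @slot seed integer seed.
#'
#' @export
setClass("EnrichmentResult",
    representation(
        observed = "integer",
        nullCounts = "integer",
        percentile = "numeric",
        call = "character",
        nPerm = "integer",
        seed = "integer"
    )
)

setValidity("EnrichmentResult", function(object) {
    msg <- NULL
    if (length(object@nullCounts) != object@nPerm)
        msg <- c(msg, "nullCounts must have length nPerm")
    if (object@percentile < 0 || object@percentile > 1)
        msg <- c(msg, "percentile must lie in [0, 1]")
    ok <- switch(object@call,
        enriched = object@percentile > 0.95,
        depleted = object@percentile < 0.05,
        ns = object@percentile <= 0.95,
        FALSE)
    if (!isTRUE(ok))
        msg <- c(msg, "call inconsistent with the 95%/5% percentile rule")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult:", object@observed,
        "introns overlap >= 1 SNP (null mean",
        format(mean(object@nullCounts), digits = 3), "over",
        object@nPerm, "control sets)\n")
    cat("  empirical percentile:", format(object@percentile, digits = 4),
        "->", object@call, "\n")
})

#' @describeIn EnrichmentResult-class the enrichment call
#'   ("enriched", "depleted" or "ns").
#' @param object an `EnrichmentResult`.
#' @export
setGeneric("enrichmentCall", function(object) standardGeneric("enrichmentCall"))

#' @export
setMethod("enrichmentCall", "EnrichmentResult", function(object) object@call)
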