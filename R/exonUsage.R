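# Differential exon usage and gene-level differential expression.
#
# The DEU model is a two-bin negative-binomial GLM per exon: the counts of
# the exon and of the rest of its gene, across samples, are modelled as
#   count ~ sample + bin + bin:run + bin:condition
# where `bin` distinguishes this-exon from rest-of-gene. The sample factor
# absorbs per-sample totals (library size, gene-level expression and
# subject effects), so the bin:condition interaction captures exactly the
# change in the exon's usage (its log-odds against the rest of the gene)
# between conditions, with the sequencing run as a usage covariate. The
# interaction is tested by likelihood ratio against the reduced model
# without bin:condition.

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment with monotonicity enforcement. NA p-values are
#' propagated and excluded from the number of tests.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values of the same length.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(p) {
    if (!is.numeric(p))
        stop("p must be numeric")
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    q <- rep(NA_real_, length(p))
    pv <- p[ok]
    m <- length(pv)
    if (m == 0L) return(q)
    o <- order(pv)
    adj <- pv[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    qv <- numeric(m)
    qv[o] <- adj
    q[ok] <- qv
    q
}

#' Flag testable exons
#'
#' Marks exons whose total count across all samples reaches `minTotal` and
#' whose gene retains at least two such exons (the this-exon versus
#' rest-of-gene formulation needs a non-degenerate "rest"). The flag is
#' stored in `rowData()$testable`.
#'
#' @param ecs an [ExonCountSet-class].
#' @param minTotal minimum summed count per exon (default 10).
#' @return `ecs` with a logical `testable` column in its `rowData`.
#' @export
filterTestable <- function(ecs, minTotal = 10L) {
    if (minTotal < 0) stop("minTotal must be >= 0")
    tot <- rowSums(assay(ecs, "counts"))
    pass <- tot >= minTotal
    nPass <- rowsum(as.integer(pass), geneIds(ecs))
    testable <- pass & (nPass[geneIds(ecs), 1L] >= 2L)
    rowData(ecs)$testable <- as.logical(testable)
    ecs
}

# Pooled method-of-moments NB dispersion per unit from replicate groups,
# shrunk 50/50 toward a mean-count-binned trend and floored at 1e-4.
# `mats` is a list of count matrices (same columns) whose per-row moments
# are pooled; `groups` assigns columns to replicate groups.
estimateDispersion <- function(mats, groups, sf) {
    groups <- as.factor(groups)
    num <- 0; den <- 0; meanCount <- 0
    for (mat in mats) {
        z <- sweep(mat, 2L, sf, "/")
        for (g in levels(groups)) {
            idx <- which(groups == g)
            if (length(idx) < 2L) next
            m <- rowMeans(z[, idx, drop = FALSE])
            v <- apply(z[, idx, drop = FALSE], 1L, var)
            num <- num + (v - m)
            den <- den + m^2
        }
        meanCount <- meanCount + rowMeans(z)
    }
    raw <- pmax(num / pmax(den, 1e-8), 1e-8)
    nbin <- min(10L, floor(length(raw) / 20L))
    trend <- if (nbin >= 2L) {
        bins <- cut(rank(meanCount, ties.method = "first"), nbin,
                    labels = FALSE)
        tapply(raw, bins, mean)[as.character(bins)]
    } else rep(mean(raw), length(raw))
    pmax(0.5 * raw + 0.5 * trend, 1e-4)
}

# Coefficient standard errors from a glm.fit object (dispersion fixed at 1).
glmFitSE <- function(fit) {
    p <- fit$rank
    Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    Rmat[lower.tri(Rmat)] <- 0
    cov <- chol2inv(Rmat)
    se <- rep(NA_real_, length(fit$coefficients))
    se[fit$qr$pivot[seq_len(p)]] <- sqrt(diag(cov))
    names(se) <- names(fit$coefficients)
    se
}

# Fit the two-bin NB GLM for one exon; returns LRT p, log2 usage fold
# change, its SE (log2 scale) and the per-level usage coefficients.
fitUsageGLM <- function(yRest, yExon, Xfull, Xred, theta, interIdx) {
    y <- c(yRest, yExon)
    fam <- MASS::negative.binomial(theta = theta)
    full <- tryCatch(suppressWarnings(
        stats::glm.fit(Xfull, y, family = fam,
                       control = list(maxit = 50))),
        error = function(e) NULL)
    red <- tryCatch(suppressWarnings(
        stats::glm.fit(Xred, y, family = fam,
                       control = list(maxit = 50))),
        error = function(e) NULL)
    if (is.null(full) || is.null(red) ||
        is.na(full$coefficients[interIdx]))
        return(list(p = NA_real_, lfc = NA_real_, se = NA_real_,
                    coefs = NULL))
    stat <- max(red$deviance - full$deviance, 0)
    list(p = pchisq(stat, df = 1L, lower.tail = FALSE),
         lfc = full$coefficients[interIdx] / log(2),
         se = glmFitSE(full)[interIdx] / log(2),
         coefs = full$coefficients)
}

# Assemble the design matrices shared by all exons of one comparison.
usageDesign <- function(condition, run) {
    n <- length(condition)
    lv <- if (is.factor(condition)) levels(condition)
        else unique(condition)
    sampleF <- factor(rep(seq_len(n), 2L))
    bin <- rep(c(0, 1), each = n)
    condF <- factor(rep(as.character(condition), 2L), levels = lv)
    runF <- factor(rep(run, 2L))
    hasRun <- nlevels(runF) > 1L
    fmlFull <- if (hasRun) ~ sampleF + bin + bin:runF + bin:condF
        else ~ sampleF + bin + bin:condF
    fmlRed <- if (hasRun) ~ sampleF + bin + bin:runF
        else ~ sampleF + bin
    df <- data.frame(sampleF = sampleF, bin = bin, condF = condF,
                     runF = runF)
    Xfull <- stats::model.matrix(fmlFull, df)
    Xred <- stats::model.matrix(fmlRed, df)
    binCols <- grep("^bin:condF", colnames(Xfull))
    list(Xfull = Xfull, Xred = Xred, binIdx = match("bin", colnames(Xfull)),
         condCols = setNames(binCols,
                             sub("^bin:condF", "", colnames(Xfull)[binCols])))
}

subsetSamples <- function(ecs, cohort, timepoints) {
    cd <- colData(ecs)
    keep <- cd$cohort == cohort & cd$timepoint %in% timepoints
    if (!any(keep))
        stop("no samples for cohort '", cohort, "' at the requested ",
             "timepoints")
    ecs[, keep]
}

#' Test differential exon usage between two time points
#'
#' For each testable exon of the given cohort, fits the two-bin NB GLM
#' (this exon versus the sum of the gene's other exons) with a sample
#' factor, a bin (exon) factor, a bin:run usage covariate and a
#' bin:condition interaction, and tests the interaction by likelihood
#' ratio. Dispersion per exon is a method-of-moments estimate pooled over
#' both bins, shrunk 50/50 toward the mean-count trend. Benjamini-Hochberg
#' correction is applied across all testable exons of the comparison;
#' q < 0.05 flags significance.
#'
#' @param ecs an [ExonCountSet-class]; [filterTestable()] is applied with
#'   its default if the `testable` flag is absent.
#' @param cohort cohort label to test.
#' @param comparison character vector of two time-point labels
#'   (A, B); fold changes are B versus A.
#'
#' @return A `DataFrame` with one row per exon: `exon_id`, `gene_id`,
#'   `tested`, usage coefficients (log2-scale exon vs rest odds) for each
#'   time point, `log2fc`, `se`, `z`, `pvalue`, `qvalue`, `significant`.
#'
#' @examples
#' gm <- simulateGeneModels(12, seed = 1)
#' sim <- simulateCounts(gm, studyDesign(), simParams(depth = 5e4), seed = 1)
#' res <- testExonUsage(sim$counts, "lean", c("confluence", "day3"))
#' head(res)
#' @export
testExonUsage <- function(ecs, cohort, comparison) {
    if (length(comparison) != 2L)
        stop("comparison must name exactly two timepoints")
    if (!"testable" %in% colnames(rowData(ecs)))
        ecs <- filterTestable(ecs)
    sub <- subsetSamples(ecs, cohort, comparison)
    cd <- colData(sub)
    for (tp in comparison)
        if (length(unique(cd$subject[cd$timepoint == tp])) < 2L)
            stop("need >= 2 subjects at timepoint '", tp, "'")
    cts <- assay(sub, "counts")
    if (any(cts != round(cts)))
        stop("counts must be integers")
    storage.mode(cts) <- "double"
    sf <- medianOfRatios(cts)
    gene <- geneIds(sub)
    testable <- rowData(sub)$testable

    geneTotals <- rowsum(cts, gene)
    rest <- geneTotals[gene, , drop = FALSE] - cts

    cond <- factor(cd$timepoint, levels = comparison)
    groups <- interaction(cond, cd$run, drop = TRUE)
    idxT <- which(testable)
    alpha <- rep(NA_real_, nrow(cts))
    if (length(idxT))
        alpha[idxT] <- estimateDispersion(
            list(cts[idxT, , drop = FALSE], rest[idxT, , drop = FALSE]),
            groups, sf)

    des <- usageDesign(cond, cd$run)
    interIdx <- des$condCols[comparison[2L]]

    n <- length(idxT)
    pv <- lfc <- se <- coefA <- coefB <- rep(NA_real_, nrow(cts))
    for (i in idxT) {
        fit <- fitUsageGLM(rest[i, ], cts[i, ], des$Xfull, des$Xred,
                           1 / alpha[i], interIdx)
        pv[i] <- fit$p; lfc[i] <- fit$lfc; se[i] <- fit$se
        if (!is.null(fit$coefs)) {
            coefA[i] <- fit$coefs[des$binIdx] / log(2)
            coefB[i] <- coefA[i] + fit$lfc
        }
    }
    q <- bhFDR(pv)
    out <- DataFrame(
        exon_id = exonIds(sub),
        gene_id = gene,
        tested = testable & !is.na(pv),
        log2fc = lfc, se = se, z = lfc / se,
        pvalue = pv, qvalue = q,
        significant = !is.na(q) & q < 0.05)
    out[[paste0("coef_", comparison[1L])]] <- coefA
    out[[paste0("coef_", comparison[2L])]] <- coefB
    metadata(out) <- list(cohort = cohort, comparison = comparison,
                          modality = "splicing")
    rownames(out) <- out$exon_id
    out
}

#' Exon usage coefficients across the full time course
#'
#' Joint two-bin NB GLM fit per testable exon over all time points of a
#' cohort (`count ~ sample + bin + bin:run + bin:timepoint`), returning one
#' log2-scale usage coefficient (exon versus rest-of-gene odds, at the
#' reference run) per time point. These are the trajectories clustered by
#' [fuzzyCMeans()].
#'
#' @param ecs an [ExonCountSet-class].
#' @param cohort cohort label.
#' @param timepoints time points to include, in order; defaults to all time
#'   points present, in `colData` order.
#'
#' @return Numeric matrix, testable exons x time points.
#' @export
usageCoefficients <- function(ecs, cohort, timepoints = NULL) {
    if (!"testable" %in% colnames(rowData(ecs)))
        ecs <- filterTestable(ecs)
    cd <- colData(ecs)
    if (is.null(timepoints))
        timepoints <- unique(cd$timepoint[cd$cohort == cohort])
    sub <- subsetSamples(ecs, cohort, timepoints)
    cd <- colData(sub)
    cts <- assay(sub, "counts")
    storage.mode(cts) <- "double"
    sf <- medianOfRatios(cts)
    gene <- geneIds(sub)
    testable <- rowData(sub)$testable
    geneTotals <- rowsum(cts, gene)
    rest <- geneTotals[gene, , drop = FALSE] - cts

    cond <- factor(cd$timepoint, levels = timepoints)
    groups <- interaction(cond, cd$run, drop = TRUE)
    idxT <- which(testable)
    alpha <- rep(NA_real_, nrow(cts))
    if (length(idxT))
        alpha[idxT] <- estimateDispersion(
            list(cts[idxT, , drop = FALSE], rest[idxT, , drop = FALSE]),
            groups, sf)
    des <- usageDesign(cond, cd$run)

    out <- matrix(NA_real_, length(idxT), length(timepoints),
                  dimnames = list(exonIds(sub)[idxT], timepoints))
    fam <- function(th) MASS::negative.binomial(theta = th)
    for (k in seq_along(idxT)) {
        i <- idxT[k]
        y <- c(rest[i, ], cts[i, ])
        fit <- tryCatch(suppressWarnings(
            stats::glm.fit(des$Xfull, y, family = fam(1 / alpha[i]),
                           control = list(maxit = 50))),
            error = function(e) NULL)
        if (is.null(fit)) next
        base <- fit$coefficients[des$binIdx]
        coefs <- rep(base, length(timepoints))
        for (tp in names(des$condCols)) {
            j <- match(tp, timepoints)
            coefs[j] <- base + fit$coefficients[des$condCols[tp]]
        }
        out[k, ] <- coefs / log(2)
    }
    out[stats::complete.cases(out), , drop = FALSE]
}

#' Test gene-level differential expression between two time points
#'
#' Sums exon counts to gene level and fits, per gene, a negative-binomial
#' GLM `count ~ condition + run` with a log size-factor offset
#' (median-of-ratios). The condition coefficient is tested by a Wald test.
#' Genes with q < 0.05 and a fold change of at least `fcThreshold` are
#' flagged significant.
#'
#' @param ecs an [ExonCountSet-class].
#' @param cohort cohort label.
#' @param comparison two time-point labels (A, B); fold change is B vs A.
#' @param fcThreshold minimum fold change (linear scale) for the
#'   significance flag; default 1.25.
#'
#' @return A `DataFrame` with one row per gene: `gene_id`, `log2fc`, `se`
#'   (log2 scale), `z`, `pvalue`, `qvalue`, `significant`.
#' @export
testGeneExpression <- function(ecs, cohort, comparison,
                               fcThreshold = 1.25) {
    if (length(comparison) != 2L)
        stop("comparison must name exactly two timepoints")
    sub <- subsetSamples(ecs, cohort, comparison)
    cd <- colData(sub)
    cts <- rowsum(assay(sub, "counts"), geneIds(sub))
    storage.mode(cts) <- "double"
    sf <- medianOfRatios(cts)
    cond <- factor(cd$timepoint, levels = comparison)
    runF <- factor(cd$run)
    groups <- interaction(cond, runF, drop = TRUE)
    alpha <- estimateDispersion(list(cts), groups, sf)

    df <- data.frame(cond = cond, runF = runF)
    fml <- if (nlevels(runF) > 1L) ~ cond + runF else ~ cond
    X <- stats::model.matrix(fml, df)
    condIdx <- match(paste0("cond", comparison[2L]), colnames(X))
    off <- log(sf)

    genes <- rownames(cts)
    lfc <- se <- pv <- rep(NA_real_, length(genes))
    for (i in seq_along(genes)) {
        fit <- tryCatch(suppressWarnings(
            stats::glm.fit(X, cts[i, ], offset = off,
                           family = MASS::negative.binomial(
                                   theta = 1 / alpha[i]),
                           control = list(maxit = 50))),
            error = function(e) NULL)
        if (is.null(fit) || is.na(fit$coefficients[condIdx])) next
        co <- fit$coefficients[condIdx]
        s <- glmFitSE(fit)[condIdx]
        lfc[i] <- co / log(2)
        se[i] <- s / log(2)
        pv[i] <- 2 * pnorm(-abs(co / s))
    }
    q <- bhFDR(pv)
    out <- DataFrame(
        gene_id = genes,
        log2fc = lfc, se = se, z = lfc / se,
        pvalue = pv, qvalue = q,
        significant = !is.na(q) & q < 0.05 &
            abs(lfc) >= log2(fcThreshold))
    metadata(out) <- list(cohort = cohort, comparison = comparison,
                          modality = "expression")
    rownames(out) <- genes
    out
}
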