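#' Simulate gene models on synthetic chromosomes
#'
#' Lays out non-overlapping multi-exon genes along synthetic chromosomes
#' (roughly `genesPerChrom` genes per chromosome), drawing the number of
#' exons, exon lengths and intron lengths uniformly from the given inclusive
#' ranges. Coordinates follow the `GRanges` convention (1-based, inclusive).
#'
#' @param nGenes number of genes (>= 1).
#' @param exonsPerGene inclusive range (or single value) for exons per gene.
#' @param exonLength inclusive range for exon lengths in bp.
#' @param intronLength inclusive range for intron lengths in bp.
#' @param genesPerChrom genes placed per synthetic chromosome.
#' @param seed integer seed; output is a pure function of the arguments.
#'
#' @return A `GRanges` of exons with metadata columns `gene_id`, `exon_id`
#'   (gene id + exon rank) and `exon_rank`, ordered by gene and rank.
#'
#' @examples
#' gm <- simulateGeneModels(5, seed = 1)
#' split(gm, gm$gene_id)
#' @export
simulateGeneModels <- function(nGenes,
                               exonsPerGene = c(2L, 8L),
                               exonLength = c(50L, 300L),
                               intronLength = c(200L, 2000L),
                               genesPerChrom = 100L,
                               seed = 1L) {
    if (!is.numeric(nGenes) || length(nGenes) != 1L || nGenes < 1)
        stop("nGenes must be a positive integer")
    nGenes <- as.integer(nGenes)
    withSeed(seed, {
        nEx <- sampleRange(nGenes, exonsPerGene, "exonsPerGene")
        interGeneGap <- max(intronLength) * 5L
        geneId <- sprintf("g%04d", seq_len(nGenes))
        chromIdx <- (seq_len(nGenes) - 1L) %/% as.integer(genesPerChrom) + 1L
        chrom <- character(0); startV <- integer(0); endV <- integer(0)
        gid <- character(0); rank <- integer(0); strandV <- character(0)
        cursor <- 1L
        lastChrom <- 0L
        for (g in seq_len(nGenes)) {
            if (chromIdx[g] != lastChrom) {
                cursor <- 1L + interGeneGap
                lastChrom <- chromIdx[g]
            }
            k <- nEx[g]
            exLen <- sampleRange(k, exonLength, "exonLength")
            inLen <- if (k > 1L)
                sampleRange(k - 1L, intronLength, "intronLength")
            else integer(0)
            st <- cursor + c(0L, cumsum(exLen[-k] + inLen))
            en <- st + exLen - 1L
            strandG <- if (runif(1) < 0.5) "+" else "-"
            chrom <- c(chrom, rep(sprintf("chrS%d", chromIdx[g]), k))
            startV <- c(startV, st)
            endV <- c(endV, en)
            gid <- c(gid, rep(geneId[g], k))
            rank <- c(rank, seq_len(k))
            strandV <- c(strandV, rep(strandG, k))
            cursor <- en[k] + 1L + interGeneGap
        }
        gr <- GRanges(chrom, IRanges(startV, endV), strand = strandV)
        mcols(gr)$gene_id <- gid
        mcols(gr)$exon_rank <- rank
        mcols(gr)$exon_id <- sprintf("%s:E%03d", gid, rank)
        names(gr) <- gr$exon_id
        gr
    })
}

#' Default simulation parameters
#'
#' Parameters controlling the exon-count simulator. Defaults describe the
#' study conditions emulated throughout the package: sequencing depth of
#' 5e6 expected exonic counts per run, moderate negative-binomial
#' overdispersion, 10% of eligible exons carrying a usage shift of
#' |log2 effect| = 1.5 per comparison (half shared across cohorts), 10% of
#' genes differentially expressed at |log2 FC| = 1, and a mild run-specific
#' library-size difference between the two sequencing runs.
#'
#' @param depth expected exonic counts per sample column (one run).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2); > 0.
#' @param dsFraction fraction of eligible exons with a planted usage shift
#'   per cohort and comparison, in [0, 1].
#' @param usageEffect |log2| usage effect size of planted shifts (exon vs
#'   rest-of-gene odds), sign randomized.
#' @param shareFraction fraction of planted effects shared identically
#'   across all cohorts, in [0, 1].
#' @param deFraction fraction of genes with planted expression changes per
#'   cohort and comparison, in [0, 1].
#' @param deEffect |log2| fold change of planted expression changes.
#' @param runLibFactors library-size factor per sequencing run (recycled to
#'   the number of runs).
#' @param subjectSd log-normal sd of subject-level gene-expression noise.
#' @param exonWeightSd log-normal sd of baseline within-gene exon weights.
#' @param geneExprSd log-normal sd of baseline gene expression.
#'
#' @return A named list of validated parameters for [simulateCounts()].
#' @export
simParams <- function(depth = 5e6,
                      dispersion = 0.05,
                      dsFraction = 0.1,
                      usageEffect = 1.5,
                      shareFraction = 0.5,
                      deFraction = 0.1,
                      deEffect = 1,
                      runLibFactors = c(1, 0.8),
                      subjectSd = 0.1,
                      exonWeightSd = 0.75,
                      geneExprSd = 1) {
    if (dispersion <= 0)
        stop("dispersion must be > 0")
    for (f in c(dsFraction, shareFraction, deFraction))
        if (f < 0 || f > 1)
            stop("fractions must lie in [0, 1]")
    if (depth <= 0) stop("depth must be > 0")
    list(depth = depth, dispersion = dispersion,
         dsFraction = dsFraction, usageEffect = usageEffect,
         shareFraction = shareFraction, deFraction = deFraction,
         deEffect = deEffect, runLibFactors = runLibFactors,
         subjectSd = subjectSd, exonWeightSd = exonWeightSd,
         geneExprSd = geneExprSd)
}

# Plant shared and cohort-specific effects for each consecutive time-point
# comparison. Returns a data.frame(cohort, comparison, id, log2Effect).
plantEffects <- function(ids, cohorts, comparisons, fraction, effectSize,
                         shareFraction) {
    out <- list()
    for (cmp in comparisons) {
        nTot <- round(fraction * length(ids))
        if (nTot == 0L) next
        nShared <- round(shareFraction * nTot)
        nSpec <- nTot - nShared
        need <- nShared + nSpec * length(cohorts)
        pool <- sample(ids, min(need, length(ids)))
        sharedIds <- head(pool, nShared)
        sharedSign <- sample(c(-1, 1), length(sharedIds), replace = TRUE)
        rest <- if (nShared > 0L) pool[-seq_len(nShared)] else pool
        for (ci in seq_along(cohorts)) {
            spec <- rest[seq_len(nSpec) + (ci - 1L) * nSpec]
            spec <- spec[!is.na(spec)]
            out[[length(out) + 1L]] <- data.frame(
                cohort = cohorts[ci], comparison = cmp,
                id = c(sharedIds, spec),
                log2Effect = c(sharedSign * effectSize,
                               sample(c(-1, 1), length(spec),
                                      replace = TRUE) * effectSize),
                stringsAsFactors = FALSE)
        }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(cohort = character(0), comparison = character(0),
                    id = character(0), log2Effect = numeric(0))
}

#' Simulate exon-level counts for a differentiation time course
#'
#' Draws negative-binomial exon counts for every combination of cohort,
#' time point, subject and sequencing run in `design`, over the exons of
#' `models`. Gene-level expression and within-gene exon usage are controlled
#' independently: each gene has a baseline expression level and each exon a
#' baseline usage weight; planted differential-usage effects shift the
#' log-odds of an exon against the rest of its gene by the stated log2
#' effect between consecutive time points (persisting to later time
#' points), and planted expression effects scale the gene mean likewise.
#' Technical runs share the subject-by-time-point biological mean and
#' differ only by the run library factor and NB sampling noise.
#'
#' @param models exon `GRanges` from [simulateGeneModels()].
#' @param design a [StudyDesign-class]; defaults to [studyDesign()].
#' @param params parameter list from [simParams()].
#' @param seed integer seed.
#'
#' @return A list with elements `counts` (an [ExonCountSet-class]) and
#'   `truth`. The truth records the planted effects (`dsExons`, `deGenes`,
#'   keyed by cohort and comparison) and, in `inducedUsage`, the exact
#'   log2 usage-odds change of every exon whose gene carries a planted
#'   shift: because an exon's usage is measured against the rest of its
#'   gene, a planted shift on one exon necessarily shifts the usage odds
#'   of its sibling exons as well, and those induced effects are part of
#'   the ground truth a usage test sees.
#'
#' @examples
#' gm <- simulateGeneModels(10, seed = 1)
#' sim <- simulateCounts(gm, studyDesign(), simParams(depth = 1e4), seed = 1)
#' sim$counts
#' head(sim$truth$dsExons)
#' @export
simulateCounts <- function(models, design = studyDesign(),
                           params = simParams(), seed = 1L) {
    stopifnot(!is.null(models$gene_id), !is.null(models$exon_id))
    geneId <- unique(models$gene_id)
    nExon <- length(models)
    tps <- design@timepoints
    cohorts <- design@cohorts
    comparisons <- paste(tps[-length(tps)], tps[-1], sep = "_vs_")

    withSeed(seed, {
        exonsPerGene <- table(models$gene_id)[models$gene_id]
        eligible <- models$exon_id[exonsPerGene >= 2L]
        dsExons <- plantEffects(eligible, cohorts, comparisons,
                                params$dsFraction, params$usageEffect,
                                params$shareFraction)
        deGenes <- plantEffects(geneId, cohorts, comparisons,
                                params$deFraction, params$deEffect,
                                params$shareFraction)

        baseExpr <- setNames(exp(rnorm(length(geneId),
                                       sd = params$geneExprSd)), geneId)
        baseWeight <- exp(rnorm(nExon, sd = params$exonWeightSd))
        norm <- sum(baseExpr)
        runFac <- rep_len(params$runLibFactors, design@runsPerSample)

        # cumulative per-timepoint log2 multipliers from planted effects
        cumEffect <- function(tbl, ids) {
            eff <- array(0, dim = c(length(ids), length(cohorts),
                                    length(tps)),
                         dimnames = list(ids, cohorts, tps))
            if (nrow(tbl) == 0L) return(eff)
            later <- match(sub(".*_vs_", "", tbl$comparison), tps)
            for (r in seq_len(nrow(tbl))) {
                i <- match(tbl$id[r], ids)
                for (t in later[r]:length(tps))
                    eff[i, tbl$cohort[r], t] <-
                        eff[i, tbl$cohort[r], t] + tbl$log2Effect[r]
            }
            eff
        }
        usageShift <- cumEffect(dsExons, models$exon_id)
        exprShift <- cumEffect(deGenes, geneId)

        geneOf <- match(models$gene_id, geneId)

        # Exact induced usage effects: a planted shift on one exon changes
        # the usage odds (this exon vs rest of gene) of every exon in the
        # gene, because the rest-of-gene denominator contains the shifted
        # exon. Record the true log2 odds change of every exon for every
        # comparison so recovery can be scored against the full set of
        # truly shifted exons.
        oddsFor <- function(co, tp) {
            w <- baseWeight * 2^usageShift[, co, tp]
            sumW <- rowsum(w, models$gene_id)[geneId, 1L]
            w / (sumW[geneOf] - w)
        }
        induced <- list()
        for (co in cohorts)
            for (ci in seq_along(comparisons)) {
                o1 <- oddsFor(co, tps[ci])
                o2 <- oddsFor(co, tps[ci + 1L])
                d <- log2(o2) - log2(o1)
                nz <- which(abs(d) > 1e-9)
                if (length(nz))
                    induced[[length(induced) + 1L]] <- data.frame(
                        cohort = co, comparison = comparisons[ci],
                        exon_id = models$exon_id[nz],
                        log2OddsChange = d[nz],
                        stringsAsFactors = FALSE)
            }
        inducedUsage <- if (length(induced)) do.call(rbind, induced)
            else data.frame(cohort = character(0),
                            comparison = character(0),
                            exon_id = character(0),
                            log2OddsChange = numeric(0))
        cols <- expand.grid(run = seq_len(design@runsPerSample),
                            timepoint = tps,
                            subject = seq_len(design@subjectsPerCohort),
                            cohort = cohorts,
                            stringsAsFactors = FALSE)
        cols <- cols[, c("cohort", "subject", "timepoint", "run")]
        sampleNames <- sprintf("%s_s%d_%s_r%d", cols$cohort, cols$subject,
                               cols$timepoint, cols$run)

        subjNoise <- array(exp(rnorm(length(geneId) * length(cohorts) *
                                     design@subjectsPerCohort,
                                     sd = params$subjectSd)),
                           dim = c(length(geneId), length(cohorts),
                                   design@subjectsPerCohort),
                           dimnames = list(geneId, cohorts, NULL))

        counts <- matrix(0L, nExon, nrow(cols),
                         dimnames = list(models$exon_id, sampleNames))
        for (j in seq_len(nrow(cols))) {
            co <- cols$cohort[j]; tp <- cols$timepoint[j]
            su <- cols$subject[j]; rn <- cols$run[j]
            w <- baseWeight * 2^usageShift[, co, tp]
            sumW <- rowsum(w, models$gene_id)[geneId, 1L]
            pi <- w / sumW[geneOf]
            gExpr <- baseExpr * 2^exprShift[, co, tp] * subjNoise[, co, su]
            mu <- params$depth * gExpr[geneOf] * pi * runFac[rn] / norm
            counts[, j] <- rnbinom(nExon, mu = mu,
                                   size = 1 / params$dispersion)
        }

        colData <- DataFrame(
            cohort = cols$cohort,
            timepoint = cols$timepoint,
            subject = sprintf("%s_s%d", cols$cohort, cols$subject),
            run = sprintf("run%d", cols$run),
            row.names = sampleNames)
        ecs <- ExonCountSet(counts, models, colData)
        names(dsExons)[names(dsExons) == "id"] <- "exon_id"
        names(deGenes)[names(deGenes) == "id"] <- "gene_id"
        list(counts = ecs,
             truth = list(dsExons = dsExons, deGenes = deGenes,
                          inducedUsage = inducedUsage,
                          seed = as.integer(seed), params = params))
    })
}

#' Simulate SNP positions with optional intronic spiking
#'
#' Places `nBackground` SNPs uniformly over the simulated genome span and,
#' optionally, `nSpiked` additional SNPs uniformly within a chosen set of
#' introns, emulating GWAS variant lists with a planted over-representation
#' in selected flanking introns. Positions are unique.
#'
#' @param models exon `GRanges` from [simulateGeneModels()].
#' @param nBackground number of background SNPs.
#' @param spikeIntrons `GRanges` of introns to receive spiked SNPs; must be
#'   introns of `models` (exact coordinate match, see [flankingIntrons()]).
#' @param nSpiked number of spiked SNPs (0 for none).
#' @param seed integer seed.
#'
#' @return A list with `snps` (width-1 `GRanges`, metadata column `label`
#'   of "background"/"spiked") and `truth` (the spiked introns and count).
#'
#' @examples
#' gm <- simulateGeneModels(10, seed = 1)
#' simulateSnps(gm, nBackground = 100, seed = 2)$snps
#' @export
simulateSnps <- function(models, nBackground, spikeIntrons = NULL,
                         nSpiked = 0L, seed = 1L) {
    nBackground <- as.integer(nBackground)
    nSpiked <- as.integer(nSpiked)
    if (nSpiked > 0L) {
        if (is.null(spikeIntrons) || length(spikeIntrons) == 0L)
            stop("nSpiked > 0 requires spikeIntrons")
        allIntrons <- flankingIntrons(models)@introns
        hit <- findOverlaps(spikeIntrons, allIntrons, type = "equal")
        if (length(unique(S4Vectors::queryHits(hit))) < length(spikeIntrons))
            stop("spikeIntrons must be introns of the gene models")
    }
    withSeed(seed, {
        spans <- tapply(end(models), as.character(seqnames(models)), max)
        spans <- spans + 1000L
        chroms <- names(spans)
        drawBackground <- function(n) {
            ch <- sample(chroms, n, replace = TRUE,
                         prob = as.numeric(spans))
            pos <- 1L + as.integer(floor(runif(n) * spans[ch]))
            GRanges(ch, IRanges(pos, width = 1L))
        }
        snps <- drawBackground(nBackground)
        if (nSpiked > 0L) {
            idx <- sample(length(spikeIntrons), nSpiked, replace = TRUE)
            pos <- start(spikeIntrons)[idx] +
                as.integer(floor(runif(nSpiked) * width(spikeIntrons)[idx]))
            spiked <- GRanges(as.character(seqnames(spikeIntrons))[idx],
                              IRanges(pos, width = 1L))
            snps <- c(snps, spiked)
        }
        label <- rep(c("background", "spiked"),
                     c(nBackground, nSpiked))
        # enforce unique positions, preserving exact counts
        key <- paste0(seqnames(snps), ":", start(snps))
        while (anyDuplicated(key)) {
            dup <- which(duplicated(key))
            bg <- dup[label[dup] == "background"]
            if (length(bg)) {
                repl <- drawBackground(length(bg))
                snps[bg] <- repl
            }
            sp <- dup[label[dup] == "spiked"]
            if (length(sp)) {
                idx <- sample(length(spikeIntrons), length(sp),
                              replace = TRUE)
                pos <- start(spikeIntrons)[idx] + as.integer(
                    floor(runif(length(sp)) * width(spikeIntrons)[idx]))
                snps[sp] <- GRanges(
                    as.character(seqnames(spikeIntrons))[idx],
                    IRanges(pos, width = 1L))
            }
            key <- paste0(seqnames(snps), ":", start(snps))
        }
        mcols(snps)$label <- label
        list(snps = snps,
             truth = list(spikeIntrons = spikeIntrons,
                          nSpiked = nSpiked,
                          seed = as.integer(seed)))
    })
}
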