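# End-to-end orchestration: simulate -> DEU/DGE -> sharing -> clustering ->
# GWAS enrichment, from a single config with per-stage seeds.

#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [runPipeline()], with
#' the analysis constants used throughout: FDR 0.05, expression fold-change
#' threshold 1.25, sharing factor 0.5, k = 6 clusters, 1000 control sets
#' and the 95%/5% percentile cuts. Any element can be overridden before
#' passing the list on (or via a YAML file with the same structure).
#'
#' @param nGenes number of simulated genes (demo-sized default 50).
#' @param seed base seed; per-stage seeds are derived as small offsets.
#' @return A nested configuration list.
#' @export
pipelineConfig <- function(nGenes = 50L, seed = 1L) {
    seed <- as.integer(seed)
    list(
        simulate = list(nGenes = as.integer(nGenes),
                        depth = 5e5,
                        dispersion = 0.05,
                        dsFraction = 0.1,
                        usageEffect = 1.5,
                        deFraction = 0.1,
                        deEffect = 1,
                        seed = seed),
        snps = list(nBackground = 200L, nSpiked = 100L,
                    seed = seed + 1L),
        deu = list(minTotal = 10L),
        thresholds = list(fdr = 0.05, fcThreshold = 1.25,
                          sharingFactor = 0.5),
        clustering = list(k = 6L, m = 2, seed = seed + 2L),
        enrichment = list(nPerm = 1000L, seed = seed + 3L)
    )
}

mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(override[[nm]]) && is.list(base[[nm]]))
            base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
        else base[[nm]] <- override[[nm]]
    }
    base
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order from one configuration:
#' simulates gene models, exon counts and SNPs (with planted ground truth),
#' tests differential exon usage and gene expression for every cohort and
#' consecutive time-point comparison, computes the three sharing matrices
#' (splicing-splicing at the exon level, expression-expression at the gene
#' level, and splicing-expression with splicing aggregated to genes),
#' clusters each cohort's differentially spliced exon trajectories, and
#' tests SNP enrichment in flanking introns per analysis. All stage
#' outputs are written under `outdir` along with `summary.json` and a
#' `manifest.json` recording seeds, parameters and output file hashes.
#' Reruns with the same configuration are deterministic.
#'
#' @param config a configuration list from [pipelineConfig()], a partial
#'   list of overrides, or the path to a YAML file of overrides.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, the summary list.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile("run"),
                        quiet = FALSE) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    config <- mergeConfig(pipelineConfig(), config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (!quiet) message("[spliceDyn] ", ...)

    ## stage 1: simulation
    say("simulating ", config$simulate$nGenes, " genes")
    design <- studyDesign()
    models <- simulateGeneModels(config$simulate$nGenes,
                                 seed = config$simulate$seed)
    params <- simParams(depth = config$simulate$depth,
                        dispersion = config$simulate$dispersion,
                        dsFraction = config$simulate$dsFraction,
                        usageEffect = config$simulate$usageEffect,
                        deFraction = config$simulate$deFraction,
                        deEffect = config$simulate$deEffect)
    sim <- simulateCounts(models, design, params,
                          seed = config$simulate$seed)
    writeGeneModels(models, file.path(outdir, "models.gff3"))
    writeCounts(sim$counts, file.path(outdir, "counts.tsv"),
                file.path(outdir, "samples.tsv"))
    writeTruth(sim$truth, file.path(outdir, "truth.json"))

    ## SNPs are spiked into the flanking introns of the exons carrying
    ## planted usage shifts in the first cohort's first comparison, so the
    ## demo has one genuinely enriched analysis against a uniform
    ## background.
    flankSet <- flankingIntrons(models)
    tps <- design@timepoints
    firstCmp <- paste(tps[1L], tps[2L], sep = "_vs_")
    truthDS <- unique(sim$truth$dsExons$exon_id[
        sim$truth$dsExons$cohort == design@cohorts[1L] &
        sim$truth$dsExons$comparison == firstCmp])
    spikeable <- flankSet@introns[unique(unlist(
        flankSet@flanks[intersect(truthDS, names(flankSet@flanks))]))]
    snpSim <- simulateSnps(models, config$snps$nBackground,
                           spikeIntrons = spikeable,
                           nSpiked = if (length(spikeable))
                               config$snps$nSpiked else 0L,
                           seed = config$snps$seed)
    writeSnps(snpSim$snps, file.path(outdir, "snps.bed"))

    ## stage 2: DEU and DGE per cohort and comparison
    ecs <- filterTestable(sim$counts, config$deu$minTotal)
    comparisons <- lapply(seq_len(length(tps) - 1L),
                          function(i) tps[c(i, i + 1L)])
    deu <- list(); dge <- list()
    for (co in design@cohorts)
        for (cmp in comparisons) {
            lab <- paste0(co, ":", cmp[1L], "_vs_", cmp[2L])
            say("testing ", lab)
            deu[[lab]] <- testExonUsage(ecs, co, cmp)
            dge[[lab]] <- testGeneExpression(
                ecs, co, cmp, config$thresholds$fcThreshold)
            utils::write.table(
                as.data.frame(deu[[lab]]),
                file.path(outdir, paste0("deu_", gsub(":", "_", lab),
                                         ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
            utils::write.table(
                as.data.frame(dge[[lab]]),
                file.path(outdir, paste0("dge_", gsub(":", "_", lab),
                                         ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }

    ## stage 3: sharing
    say("computing sharing matrices")
    fac <- config$thresholds$sharingFactor
    shSplice <- sharingMatrix(collectEffects(deu, "exon_id"), fac)
    shExpr <- sharingMatrix(collectEffects(dge, "gene_id"), fac)
    deuGene <- lapply(deu, aggregateToGene)
    names(deuGene) <- paste0("splicing|", names(deu))
    dgeG <- dge
    names(dgeG) <- paste0("expression|", names(dge))
    shCross <- sharingMatrix(collectEffects(c(deuGene, dgeG), "gene_id"),
                             fac)
    for (x in list(list(shSplice, "sharing_splicing.tsv"),
                   list(shExpr, "sharing_expression.tsv"),
                   list(shCross, "sharing_cross.tsv")))
        utils::write.table(sharingFractions(x[[1L]]),
                           file.path(outdir, x[[2L]]), sep = "\t",
                           quote = FALSE, col.names = NA)

    ## stage 4: clustering per cohort
    clusters <- list()
    for (co in design@cohorts) {
        labs <- grep(paste0("^", co, ":"), names(deu), value = TRUE)
        ids <- selectClusterInput(deu[labs])
        if (length(ids) < config$clustering$k) {
            say("cohort ", co, ": too few DS exons to cluster (",
                length(ids), ")")
            next
        }
        say("clustering ", length(ids), " exons for ", co)
        traj <- usageCoefficients(ecs, co, tps)
        traj <- traj[intersect(ids, rownames(traj)), , drop = FALSE]
        scaled <- suppressWarnings(centerScale(traj))
        if (nrow(scaled) < config$clustering$k) next
        model <- fuzzyCMeans(scaled, k = config$clustering$k,
                             m = config$clustering$m,
                             seed = config$clustering$seed)
        asg <- clusterAssignments(model)
        clusters[[co]] <- list(model = model, assignments = asg)
        utils::write.table(
            data.frame(exon_id = names(asg$assignments),
                       cluster = asg$assignments),
            file.path(outdir, paste0("clusters_", co, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(centroids(model),
            file.path(outdir, paste0("centroids_", co, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }

    ## stage 5: GWAS enrichment per analysis
    enrich <- list()
    for (lab in names(deu)) {
        r <- deu[[lab]]
        ds <- as.character(r$exon_id[r$significant])
        tested <- as.character(r$exon_id[r$tested])
        if (length(ds) < 2L) next
        enrich[[lab]] <- permutationEnrichment(
            ds, tested, flankSet, snpSim$snps,
            nPerm = config$enrichment$nPerm,
            seed = config$enrichment$seed)
    }

    ## summary + manifest
    summary <- list(
        nGenes = config$simulate$nGenes,
        nExons = nrow(ecs),
        nTestable = sum(rowData(ecs)$testable),
        nSignificantDEU = lapply(deu, function(r) sum(r$significant)),
        nSignificantDGE = lapply(dge, function(r) sum(r$significant)),
        sharingSplicing = round(sharingFractions(shSplice), 10),
        sharingExpression = round(sharingFractions(shExpr), 10),
        sharingCross = round(sharingFractions(shCross), 10),
        clusterPrevalence = lapply(clusters, function(cl)
            round(cl$assignments$prevalence, 10)),
        enrichment = lapply(enrich, function(e) list(
            observed = e@observed,
            nullMean = round(mean(e@nullCounts), 10),
            percentile = e@percentile,
            call = enrichmentCall(e)))
    )
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
    manifest <- list(
        package = "spliceDyn",
        version = as.character(utils::packageVersion("spliceDyn")),
        config = config,
        outputs = as.list(setNames(
            as.character(tools::md5sum(file.path(outdir, outputs))),
            outputs)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("done: ", outdir)
    invisible(summary)
}
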