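test_that("gene model layout follows the requested geometry", {
    gm <- simulateGeneModels(1, exonsPerGene = 3, exonLength = 100,
                             intronLength = 100, seed = 5)
    expect_length(gm, 3L)
    expect_equal(width(gm), rep(100L, 3))
    s <- start(gm)[1]
    expect_equal(start(gm), c(s, s + 200L, s + 400L))
    expect_equal(gm$exon_rank, 1:3)
    expect_equal(unique(gm$gene_id), "g0001")
})

test_that("gene models are deterministic, non-overlapping, multi-chrom", {
    gm1 <- simulateGeneModels(120, seed = 3)
    gm2 <- simulateGeneModels(120, seed = 3)
    expect_identical(gm1, gm2)
    expect_gt(length(unique(as.character(seqnames(gm1)))), 1L)
    byGene <- split(gm1, gm1$gene_id)
    expect_true(all(vapply(byGene, function(g)
        all(diff(start(g)) > 0) && isDisjoint(g), logical(1))))
    hits <- findOverlaps(gm1, ignore.strand = TRUE)
    expect_true(all(S4Vectors::queryHits(hits) ==
                    S4Vectors::subjectHits(hits)))
})

test_that("gene model parameter errors are caught", {
    expect_error(simulateGeneModels(0), "nGenes")
    expect_error(simulateGeneModels(2, exonLength = c(-5, 10), seed = 1),
                 "positive")
    expect_error(simulateGeneModels(2, intronLength = 0, seed = 1),
                 "positive")
})

test_that("simulated counts are deterministic integers with valid truth", {
    gm <- simulateGeneModels(15, seed = 2)
    p <- simParams(depth = 2e4)
    s1 <- simulateCounts(gm, studyDesign(), p, seed = 7)
    s2 <- simulateCounts(gm, studyDesign(), p, seed = 7)
    expect_identical(assay(s1$counts), assay(s2$counts))
    expect_identical(s1$truth, s2$truth)
    cts <- assay(s1$counts)
    expect_true(all(cts >= 0))
    expect_identical(storage.mode(cts), "integer")
    expect_equal(ncol(cts), 3 * 3 * 3 * 2)
    # every planted id resolves to a simulated feature
    expect_true(all(s1$truth$dsExons$exon_id %in% gm$exon_id))
    expect_true(all(s1$truth$deGenes$gene_id %in% gm$gene_id))
    expect_true(all(s1$truth$dsExons$log2Effect != 0))
})

test_that("simulation parameter errors are caught", {
    expect_error(simParams(dispersion = 0), "dispersion")
    expect_error(simParams(dsFraction = 1.2), "fractions")
    expect_error(simParams(depth = -1), "depth")
})

test_that("NB mean-variance relationship matches the stated dispersion", {
    # method-of-moments on many draws at a fixed mean
    gm <- simulateGeneModels(1, exonsPerGene = 2, exonLength = 100,
                             intronLength = 100, seed = 1)
    alpha <- 0.1
    draws <- spliceDyn:::withSeed(11,
        rnbinom(10000, mu = 500, size = 1 / alpha))
    alphaHat <- (var(draws) - mean(draws)) / mean(draws)^2
    expect_lt(abs(alphaHat - alpha) / alpha, 0.1)
})

test_that("a planted usage effect shifts the exon's share as specified", {
    # log2 effect of 1 doubles the exon:rest odds between the timepoints
    design <- studyDesign(cohorts = "lean",
                          timepoints = c("confluence", "day3"),
                          subjectsPerCohort = 25L, runsPerSample = 1L)
    gm <- simulateGeneModels(30, exonsPerGene = 4, seed = 4)
    p <- simParams(depth = 1e6, dsFraction = 0.15, usageEffect = 1,
                   shareFraction = 1, deFraction = 0, subjectSd = 0)
    sim <- simulateCounts(gm, design, p, seed = 9)
    cts <- assay(sim$counts)
    cd <- colData(sim$counts)
    gene <- geneIds(sim$counts)
    rest <- rowsum(cts, gene)[gene, ] - cts
    odds <- function(tp) {
        idx <- cd$timepoint == tp
        rowSums(cts[, idx]) / rowSums(rest[, idx])
    }
    ratio <- log2(odds("day3")) - log2(odds("confluence"))
    truth <- sim$truth$dsExons
    planted <- match(truth$exon_id, exonIds(sim$counts))
    expect_gt(length(planted), 3)
    # low-usage exons have few counts and are noisy; the typical planted
    # exon doubles its odds to within sampling error
    expect_lt(median(abs(ratio[planted] - truth$log2Effect)), 0.1)
    expect_lt(max(abs(ratio[planted] - truth$log2Effect)), 0.6)
    # induced sibling effects are recorded and match the empirical shifts
    ind <- sim$truth$inducedUsage
    sib <- ind[!(ind$exon_id %in% truth$exon_id), ]
    sibIdx <- match(sib$exon_id, exonIds(sim$counts))
    expect_lt(median(abs(ratio[sibIdx] - sib$log2OddsChange)), 0.25)
})

test_that("zero planted effects leave no systematic usage shift", {
    design <- smallDesign()
    gm <- simulateGeneModels(60, exonsPerGene = 4, seed = 6)
    p <- simParams(depth = 1e5, dsFraction = 0, deFraction = 0)
    sim <- simulateCounts(gm, design, p, seed = 3)
    expect_equal(nrow(sim$truth$dsExons), 0L)
    res <- testExonUsage(sim$counts, "lean", c("confluence", "day3"))
    pv <- res$pvalue[res$tested]
    ks <- suppressWarnings(stats::ks.test(pv, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("simulated SNPs are unique, in range, and deterministic", {
    gm <- simulateGeneModels(25, seed = 8)
    s1 <- simulateSnps(gm, 400, seed = 13)
    s2 <- simulateSnps(gm, 400, seed = 13)
    expect_identical(s1$snps, s2$snps)
    snps <- s1$snps
    expect_length(snps, 400L)
    expect_true(all(width(snps) == 1L))
    key <- paste0(seqnames(snps), ":", start(snps))
    expect_false(anyDuplicated(key) > 0)
})

test_that("spiked SNPs land inside the requested introns", {
    gm <- simulateGeneModels(25, seed = 8)
    fl <- flankingIntrons(gm)
    spike <- fl@introns[1:5]
    s <- simulateSnps(gm, 50, spikeIntrons = spike, nSpiked = 30,
                      seed = 21)
    spiked <- s$snps[s$snps$label == "spiked"]
    expect_length(spiked, 30L)
    expect_true(all(countOverlaps(spiked, spike) >= 1L))
    # non-intronic interval rejected
    bogus <- GRanges("chrS1", IRanges(5, 8))
    expect_error(simulateSnps(gm, 10, spikeIntrons = bogus, nSpiked = 2,
                              seed = 1), "introns")
})

test_that("background SNP density in flanks matches genome density", {
    dens <- replicate(20, {
        seed <- sample.int(1e6, 1)
        gm <- simulateGeneModels(40, seed = seed)
        s <- simulateSnps(gm, 2000, seed = seed + 1)
        fl <- flankingIntrons(gm)
        inFlank <- sum(countOverlaps(s$snps, fl@introns) > 0)
        flankSpan <- sum(width(IRanges::reduce(fl@introns)))
        genomeSpan <- sum(tapply(end(gm), as.character(seqnames(gm)),
                                 max) + 1000)
        (inFlank / flankSpan) / (2000 / genomeSpan)
    })
    expect_lt(abs(mean(dens) - 1), 0.1)
})
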