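test_that("BH step-up matches the hand computation and p.adjust", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFDR(0.3), 0.3)
    expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
    expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
    set.seed(1)
    for (i in 1:5) {
        p <- runif(sample(2:200, 1))
        expect_equal(bhFDR(p), stats::p.adjust(p, "BH"))
    }
    # NA pass-through
    p <- c(0.01, NA, 0.5)
    q <- bhFDR(p)
    expect_true(is.na(q[2]))
    expect_equal(q[c(1, 3)], stats::p.adjust(p[c(1, 3)], "BH"))
})

test_that("testability filtering follows the count and gene rules", {
    ecs <- flatUsageEcs()
    cts <- assay(ecs)
    cts[1, ] <- 0L                       # all-zero exon
    gm <- rowRanges(ecs)
    ecs0 <- ExonCountSet(cts, gm, colData(ecs))
    f <- filterTestable(ecs0, 10)
    expect_false(rowData(f)$testable[1])
    expect_true(all(rowData(f)$testable[-1]))
    # min_total = 0 retains everything with >= 2 exons per gene
    f0 <- filterTestable(ecs0, 0)
    expect_true(all(rowData(f0)$testable))
    # single-exon gene untestable for usage
    one <- ecs0[c(1, 4:6), ]
    f1 <- filterTestable(one, 0)
    expect_false(rowData(f1)$testable[1])
    expect_error(filterTestable(ecs0, -1), "minTotal")
})

test_that("identical usage shares give no usage signal", {
    ecs <- flatUsageEcs()
    res <- testExonUsage(ecs, "lean", c("A", "B"))
    expect_true(all(res$tested))
    expect_lt(max(abs(res$log2fc)), 1e-6)
    expect_true(all(res$pvalue > 0.99))
})

test_that("design errors are reported", {
    ecs <- flatUsageEcs()
    expect_error(testExonUsage(ecs, "lean", c("A", "C")), "subjects")
    expect_error(testExonUsage(ecs, "nosuch", c("A", "B")), "no samples")
    expect_error(testExonUsage(ecs, "lean", "A"), "two timepoints")
    # non-integer counts are rejected at container construction
    cts <- assay(ecs)
    storage.mode(cts) <- "double"
    cts[1, 1] <- 3.5
    expect_error(
        methods::validObject(methods::new(
            "ExonCountSet",
            SummarizedExperiment::SummarizedExperiment(
                assays = list(counts = cts),
                rowRanges = rowRanges(ecs),
                colData = colData(ecs)))))
})

test_that("swapping the comparison negates fold changes, keeps p-values", {
    gm <- simulateGeneModels(20, seed = 31)
    sim <- simulateCounts(gm, smallDesign(),
                          simParams(depth = 5e4, dsFraction = 0.1),
                          seed = 32)
    ab <- testExonUsage(sim$counts, "lean", c("confluence", "day3"))
    ba <- testExonUsage(sim$counts, "lean", c("day3", "confluence"))
    i <- ab$tested & ba$tested
    expect_equal(ab$log2fc[i], -ba$log2fc[i], tolerance = 1e-6)
    expect_equal(ab$pvalue[i], ba$pvalue[i], tolerance = 1e-6)
})

test_that("a pure library-size run effect changes no significance call", {
    gm <- simulateGeneModels(20, seed = 41)
    sim <- simulateCounts(gm, smallDesign(),
                          simParams(depth = 5e4, dsFraction = 0.1),
                          seed = 42)
    res1 <- testExonUsage(sim$counts, "lean", c("confluence", "day3"))
    cts <- assay(sim$counts)
    run2 <- colData(sim$counts)$run == "run2"
    cts[, run2] <- 2L * cts[, run2]
    doubled <- ExonCountSet(cts, rowRanges(sim$counts),
                            colData(sim$counts))
    res2 <- testExonUsage(doubled, "lean", c("confluence", "day3"))
    expect_identical(res1$significant, res2$significant)
})

test_that("GLM p-values agree with a label-permutation oracle", {
    gm <- simulateGeneModels(2, exonsPerGene = 3, seed = 51)
    design <- smallDesign(subjects = 3L, runs = 2L)
    sim <- simulateCounts(gm, design,
                          simParams(depth = 2e4, dsFraction = 0.4,
                                    usageEffect = 0.7, deFraction = 0,
                                    subjectSd = 0),
                          seed = 52)
    ecs <- sim$counts
    obs <- testExonUsage(ecs, "lean", c("confluence", "day3"))
    cd <- colData(ecs)
    B <- 500L
    set.seed(53)
    permP <- matrix(0L, nrow(obs), B)
    for (b in seq_len(B)) {
        cdp <- cd
        for (r in unique(cd$run)) {      # permute labels within run
            idx <- which(cd$run == r)
            cdp$timepoint[idx] <- sample(cd$timepoint[idx])
        }
        ecsP <- ExonCountSet(assay(ecs), rowRanges(ecs), cdp)
        rp <- testExonUsage(ecsP, "lean", c("confluence", "day3"))
        permP[, b] <- rp$pvalue <= obs$pvalue
    }
    pPerm <- (1 + rowSums(permP)) / (B + 1)
    for (i in which(obs$tested)) {
        band <- 1.96 * sqrt(pPerm[i] * (1 - pPerm[i]) / B) + 0.05
        expect_lt(abs(obs$pvalue[i] - pPerm[i]), band + 0.05)
    }
})

test_that("usage coefficients track constant and monotone trajectories", {
    design <- studyDesign(cohorts = "lean",
                          timepoints = c("confluence", "day3", "day15"))
    gm <- simulateGeneModels(30, exonsPerGene = 4, seed = 61)
    sim <- simulateCounts(gm, design,
                          simParams(depth = 2e5, dsFraction = 0.1,
                                    shareFraction = 1, deFraction = 0),
                          seed = 62)
    co <- usageCoefficients(sim$counts, "lean")
    expect_equal(ncol(co), 3L)
    expect_true(all(colnames(co) == c("confluence", "day3", "day15")))
    truth <- sim$truth$dsExons
    # exon planted upward in both consecutive comparisons rises monotonely
    both <- intersect(
        truth$exon_id[truth$comparison == "confluence_vs_day3" &
                      truth$log2Effect > 0],
        truth$exon_id[truth$comparison == "day3_vs_day15" &
                      truth$log2Effect > 0])
    for (e in intersect(both, rownames(co)))
        expect_true(all(diff(co[e, ]) > 0))
    # unplanted exons in unaffected genes are flat up to fit noise
    affected <- unique(c(sim$truth$inducedUsage$exon_id))
    flat <- setdiff(rownames(co), affected)
    expect_lt(max(apply(co[flat, , drop = FALSE], 1,
                        function(x) diff(range(x)))), 1)
})

test_that("gene-level expression test applies the dual significance rule", {
    gm <- simulateGeneModels(40, seed = 71)
    sim <- simulateCounts(gm, smallDesign(),
                          simParams(depth = 1e5, dsFraction = 0,
                                    deFraction = 0.15, deEffect = 1.5),
                          seed = 72)
    res <- testGeneExpression(sim$counts, "lean", c("confluence", "day3"))
    expect_true(all(res$qvalue >= 0, na.rm = TRUE))
    # the flag is exactly q < 0.05 AND |FC| >= 1.25
    expect_identical(res$significant,
                     !is.na(res$qvalue) & res$qvalue < 0.05 &
                         abs(res$log2fc) >= log2(1.25))
    truth <- sim$truth$deGenes
    truthSet <- truth$gene_id[truth$cohort == "lean"]
    expect_gt(mean(truthSet %in% res$gene_id[res$significant]), 0.7)
    # z sign equals fold-change sign
    i <- !is.na(res$z)
    expect_true(all(sign(res$z[i]) == sign(res$log2fc[i])))
})

test_that("a strong fold change below 1.25 is never flagged", {
    gm <- simulateGeneModels(40, seed = 81)
    sim <- simulateCounts(gm, smallDesign(subjects = 6L),
                          simParams(depth = 2e5, dsFraction = 0,
                                    deFraction = 0.2, deEffect = 0.15),
                          seed = 82)
    res <- testGeneExpression(sim$counts, "lean", c("confluence", "day3"))
    small <- abs(res$log2fc) < log2(1.25)
    expect_false(any(res$significant[small]))
})
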