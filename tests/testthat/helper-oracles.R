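# Shared fixtures and independent brute-force oracles used across tests.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
})

# Two-timepoint, one-cohort design used by most DEU tests.
smallDesign <- function(subjects = 3L, runs = 2L)
    studyDesign(cohorts = "lean", timepoints = c("confluence", "day3"),
                subjectsPerCohort = subjects, runsPerSample = runs)

# Hand-built ExonCountSet with identical usage shares in every sample
# (exon:rest 100:900 within each gene).
flatUsageEcs <- function(nGenes = 2L, nExons = 3L) {
    perExon <- c(100L, 300L, 600L)[seq_len(nExons)]
    cols <- expand.grid(subject = 1:2, run = 1:2, tp = c("A", "B"))
    counts <- matrix(rep(rep(perExon, nGenes), nrow(cols)),
                     nrow = nGenes * nExons)
    gm <- GRanges(rep("chr1", nGenes * nExons),
                  IRanges(start = seq(1, by = 1000,
                                      length.out = nGenes * nExons),
                          width = 100))
    gm$gene_id <- rep(sprintf("g%02d", seq_len(nGenes)), each = nExons)
    gm$exon_rank <- rep(seq_len(nExons), nGenes)
    gm$exon_id <- sprintf("%s:E%03d", gm$gene_id, gm$exon_rank)
    cd <- DataFrame(cohort = "lean", timepoint = as.character(cols$tp),
                    subject = paste0("s", cols$subject,
                                     cols$tp),
                    run = paste0("run", cols$run),
                    row.names = sprintf("s%d_%s_r%d", cols$subject,
                                        cols$tp, cols$run))
    ExonCountSet(counts, gm, cd)
}

# Brute-force double-loop implementation of the sharing criterion.
naiveSharing <- function(effA, effB, sigA, sigB, factor = 0.5) {
    num <- 0L; den <- 0L
    for (i in seq_along(effA)) {
        if (is.na(effA[i]) || is.na(effB[i])) next
        if (!(isTRUE(sigA[i]) || isTRUE(sigB[i]))) next
        den <- den + 1L
        a <- effA[i]; b <- effB[i]
        if (a == 0 || b == 0) next
        if (sign(a) != sign(b)) next
        if (max(abs(a), abs(b)) * factor <= min(abs(a), abs(b)))
            num <- num + 1L
    }
    if (den == 0L) NA_real_ else num / den
}

# Naive all-pairs scan: number of introns containing >= 1 SNP
# (deduplicated by identical coordinates).
naiveIntronHits <- function(introns, snps) {
    key <- paste0(seqnames(introns), ":", start(introns), "-",
                  end(introns))
    uniq <- !duplicated(key)
    ic <- as.character(seqnames(introns))[uniq]
    is <- start(introns)[uniq]; ie <- end(introns)[uniq]
    sc <- as.character(seqnames(snps)); sp <- start(snps)
    hits <- 0L
    for (j in seq_along(is)) {
        if (any(sc == ic[j] & sp >= is[j] & sp <= ie[j]))
            hits <- hits + 1L
    }
    hits
}

# Six template trajectory shapes plus Gaussian noise, standardized.
templateTrajectories <- function(nPer = 100L, sd = 0.3, seed = 1L) {
    templates <- rbind(c(-1, 0, 1), c(1, 0, -1), c(-1, 1, 0),
                       c(1, -1, 0), c(0, -1, 1), c(0, 1, -1))
    set.seed(seed)
    x <- templates[rep(1:6, each = nPer), ] +
        matrix(rnorm(6 * nPer * 3, sd = sd), 6 * nPer)
    rownames(x) <- sprintf("t%04d", seq_len(nrow(x)))
    list(x = centerScale(x), truth = rep(1:6, each = nPer))
}

# Assignment accuracy after matching predicted clusters to true labels
# (best per-true-cluster match; greedy on the confusion matrix).
matchedAccuracy <- function(truth, pred) {
    tab <- table(truth, pred)
    acc <- 0L
    for (step in seq_len(min(dim(tab)))) {
        ij <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
        acc <- acc + tab[ij[1L], ij[2L]]
        tab[ij[1L], ] <- -1L
        tab[, ij[2L]] <- -1L
    }
    acc / length(truth)
}
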