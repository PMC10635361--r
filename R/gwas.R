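# SNP enrichment in the flanking introns of differentially spliced exons.

#' Flanking introns of exons
#'
#' Derives, from a flattened exon annotation, the intronic interval(s)
#' immediately upstream and downstream of each exon within its gene model:
#' for exon i with neighbours, the gaps to exons i - 1 and i + 1; terminal
#' exons yield one flank and single-exon genes none. Intervals are
#' strandless (coordinates only). Introns shared by adjacent exons are
#' stored once, identified by id.
#'
#' @param models exon `GRanges` with `gene_id` and `exon_id` metadata
#'   columns, exons of a gene non-overlapping.
#' @param exonIds optional character vector restricting the exon -> flank
#'   map (the intron set always covers all genes touched); unknown ids are
#'   an error.
#' @return An [IntronFlankSet-class].
#'
#' @examples
#' gm <- simulateGeneModels(3, seed = 1)
#' flankingIntrons(gm)
#' @export
flankingIntrons <- function(models, exonIds = NULL) {
    stopifnot(!is.null(models$gene_id), !is.null(models$exon_id))
    if (!is.null(exonIds)) {
        bad <- setdiff(exonIds, models$exon_id)
        if (length(bad))
            stop("unknown exon ids: ", paste(head(bad, 3L), collapse = ", "))
    }
    o <- order(models$gene_id, start(models))
    gm <- models[o]
    gid <- gm$gene_id
    n <- length(gm)
    sameGene <- n > 1L & c(gid[-1] == gid[-n], FALSE)
    upIdx <- which(sameGene)           # intron between exon i and i+1
    intrStart <- end(gm)[upIdx] + 1L
    intrEnd <- start(gm)[upIdx + 1L] - 1L
    ok <- intrEnd >= intrStart
    upIdx <- upIdx[ok]
    introns <- GRanges(as.character(seqnames(gm))[upIdx],
                       IRanges(intrStart[ok], intrEnd[ok]))
    names(introns) <- sprintf("%s:I%03d", gid[upIdx],
                              seq_along(upIdx) -
                                  match(gid[upIdx], gid[upIdx]) + 1L)
    # per-exon flank ids: intron j links exon upIdx[j] (downstream flank)
    # and exon upIdx[j] + 1 (upstream flank)
    flanks <- vector("list", n)
    for (j in seq_along(upIdx)) {
        i <- upIdx[j]
        flanks[[i]] <- c(flanks[[i]], names(introns)[j])
        flanks[[i + 1L]] <- c(flanks[[i + 1L]], names(introns)[j])
    }
    names(flanks) <- gm$exon_id
    if (!is.null(exonIds))
        flanks <- flanks[exonIds]
    flanks[vapply(flanks, is.null, logical(1))] <-
        list(character(0))
    new("IntronFlankSet", introns = introns,
        flanks = CharacterList(flanks))
}

#' Count introns overlapping at least one SNP
#'
#' The number of distinct flanking-intron intervals (deduplicated by
#' identical coordinates) that contain one or more SNPs. A SNP at position
#' p hits an intron iff it lies within the interval on the same chromosome;
#' an intron with several SNPs counts once.
#'
#' @param flankSet an [IntronFlankSet-class].
#' @param snps width-1 `GRanges` of SNP positions.
#' @param exonIds optional subset of exons whose flanks to count; default
#'   all exons in the set.
#' @return Integer count.
#' @export
countIntronHits <- function(flankSet, snps, exonIds = NULL) {
    pre <- precomputeHits(flankSet, snps)
    ids <- if (is.null(exonIds)) names(flankSet@flanks) else exonIds
    countHitsFromIndex(pre, ids)
}

# Per-exon integer codes of its SNP-hit flanking introns (coded by
# coordinates, so introns with identical coordinates share a code), reused
# across permutations. Counting hits for an exon set is then the number of
# distinct codes over the set.
precomputeHits <- function(flankSet, snps) {
    introns <- flankSet@introns
    fl <- flankSet@flanks
    hit <- countOverlaps(introns, snps, ignore.strand = TRUE) > 0L
    coordKey <- paste0(seqnames(introns), ":", start(introns), "-",
                       end(introns))
    code <- match(coordKey, unique(coordKey))
    ul <- unlist(fl, use.names = FALSE)
    ii <- match(ul, names(introns))
    grp <- rep(seq_along(fl), lengths(fl))
    sel <- hit[ii]
    hitCodes <- rep(list(integer(0)), length(fl))
    if (any(sel)) {
        st <- split(code[ii][sel], grp[sel])
        hitCodes[as.integer(names(st))] <- lapply(st, unique)
    }
    names(hitCodes) <- names(fl)
    list(hitCodes = hitCodes)
}

countHitsFromIndex <- function(pre, exons) {
    length(unique(unlist(pre$hitCodes[exons], use.names = FALSE)))
}

#' Permutation test for SNP enrichment in flanking introns
#'
#' Compares the number of flanking introns of the differentially spliced
#' exons that overlap at least one SNP against `nPerm` control sets of the
#' same number of exons sampled (without replacement) from all tested
#' exons. The empirical percentile is the fraction of null counts strictly
#' below the observed count. A set is called enriched when the observed
#' count exceeds more than 95% of the null, and depleted when more than
#' 95% of the null exceeds it; ties between observed and null counts count
#' against both calls (conservative).
#'
#' @param dsExons character vector of differentially spliced exon ids.
#' @param testedExons character vector of all tested exon ids (superset of
#'   `dsExons`).
#' @param models exon `GRanges` (gene models), or an
#'   [IntronFlankSet-class] precomputed from them.
#' @param snps width-1 `GRanges` of SNP positions.
#' @param nPerm number of control sets (default 1000).
#' @param seed integer seed.
#' @return An [EnrichmentResult-class].
#'
#' @examples
#' gm <- simulateGeneModels(20, seed = 1)
#' snps <- simulateSnps(gm, 500, seed = 2)$snps
#' tested <- gm$exon_id
#' permutationEnrichment(sample(tested, 10), tested, gm, snps,
#'                       nPerm = 100, seed = 3)
#' @export
permutationEnrichment <- function(dsExons, testedExons, models, snps,
                                  nPerm = 1000L, seed = 1L) {
    dsExons <- as.character(dsExons)
    testedExons <- as.character(testedExons)
    if (!all(dsExons %in% testedExons))
        stop("dsExons must be a subset of testedExons")
    flankSet <- if (is(models, "IntronFlankSet")) models
        else flankingIntrons(models)
    pre <- precomputeHits(flankSet, snps)
    observed <- countHitsFromIndex(pre, dsExons)
    nDS <- length(dsExons)
    testedIdx <- match(testedExons, names(pre$hitCodes))
    if (anyNA(testedIdx))
        stop("testedExons absent from the gene models")
    nullCounts <- withSeed(seed, {
        vapply(seq_len(nPerm), function(i)
            countHitsFromIndex(pre,
                               testedIdx[sample.int(length(testedIdx),
                                                    nDS)]),
            integer(1))
    })
    percentile <- mean(nullCounts < observed)
    fracAbove <- mean(nullCounts > observed)
    # ties between observed and null counts count against both calls
    call <- if (percentile > 0.95) "enriched"
        else if (fracAbove > 0.95) "depleted" else "ns"
    new("EnrichmentResult",
        observed = as.integer(observed),
        nullCounts = as.integer(nullCounts),
        percentile = percentile,
        call = call,
        nPerm = as.integer(nPerm),
        seed = as.integer(seed))
}
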