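# Fuzzy c-means clustering of exon usage trajectories.

#' Select exons for trajectory clustering
#'
#' The union of exons significantly differentially spliced (q < 0.05) in
#' either of a cohort's two consecutive time-point comparisons.
#'
#' @param results list of per-comparison result `DataFrame`s from
#'   [testExonUsage()] for one cohort.
#' @return Character vector of exon ids, sorted.
#' @export
selectClusterInput <- function(results) {
    ids <- unlist(lapply(results, function(r)
        as.character(r$exon_id[r$significant %in% TRUE])))
    sort(unique(ids))
}

#' Center and scale usage trajectories
#'
#' Standardizes each row (exon) of a trajectory matrix to mean 0 and sample
#' standard deviation 1 (n - 1 denominator), to compare trajectory shapes
#' irrespective of magnitude. Constant rows carry no shape and are dropped
#' with a warning.
#'
#' @param x numeric matrix, exons x time points.
#' @return The standardized matrix (possibly fewer rows); dropped exon ids
#'   are recorded in `attr(, "dropped")`.
#' @examples
#' centerScale(rbind(a = c(2, 4, 6)))
#' @export
centerScale <- function(x) {
    x <- as.matrix(x)
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, sd)
    keep <- sdv > 0 & !is.na(sdv)
    if (any(!keep))
        warning(sum(!keep), " constant trajectories dropped")
    out <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    attr(out, "dropped") <- rownames(x)[!keep]
    out
}

# Squared Euclidean distances points x centroids.
sqDist <- function(x, centers) {
    outer(rowSums(x^2), rep(1, nrow(centers))) +
        outer(rep(1, nrow(x)), rowSums(centers^2)) -
        2 * tcrossprod(x, centers)
}

# k-means++-style centroid seeding.
seedCentroids <- function(x, k) {
    n <- nrow(x)
    idx <- integer(k)
    idx[1L] <- sample.int(n, 1L)
    if (k > 1L) for (j in 2:k) {
        d <- do.call(pmin, lapply(idx[seq_len(j - 1L)], function(i)
            rowSums(sweep(x, 2L, x[i, ])^2)))
        d[idx[seq_len(j - 1L)]] <- 0
        if (sum(d) == 0)
            idx[j] <- sample.int(n, 1L)
        else
            idx[j] <- sample.int(n, 1L, prob = d)
    }
    x[idx, , drop = FALSE]
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means by alternating optimization: memberships
#' u_ij proportional to (1 / d_ij^2)^(1 / (m - 1)) normalized over clusters,
#' centroids the u^m-weighted means, iterated until the objective
#' sum(u^m d^2) changes by less than `tol` or `maxIter` is reached. A point
#' coinciding exactly with a centroid receives membership 1 there. The best
#' of `nStart` k-means++-seeded restarts (by final objective) is returned.
#'
#' @param x numeric matrix, points x dimensions (standardized trajectories).
#' @param k number of clusters (default 6).
#' @param m fuzzifier > 1 (default 2).
#' @param tol convergence tolerance on the objective (default 1e-9).
#' @param maxIter maximum iterations per restart (default 1000).
#' @param nStart number of random restarts (default 5).
#' @param seed integer seed for initialization.
#' @return A [FuzzyClusterModel-class].
#'
#' @examples
#' x <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 5), 20))
#' fuzzyCMeans(x, k = 2, seed = 1)
#' @export
fuzzyCMeans <- function(x, k = 6L, m = 2, tol = 1e-9, maxIter = 1000L,
                        nStart = 5L, seed = 1L) {
    x <- as.matrix(x)
    n <- nrow(x)
    if (k < 1L) stop("k must be >= 1")
    if (m <= 1) stop("fuzzifier m must be > 1")
    if (nrow(unique(x)) < k)
        stop("need at least k distinct points")
    expo <- 1 / (m - 1)

    runOnce <- function() {
        centers <- seedCentroids(x, k)
        obj <- numeric(0)
        prev <- Inf
        for (it in seq_len(maxIter)) {
            d <- pmax(sqDist(x, centers), 0)
            u <- matrix(0, n, k)
            zero <- d < .Machine$double.eps
            anyZero <- rowSums(zero) > 0L
            if (any(anyZero))
                for (i in which(anyZero))
                    u[i, which(zero[i, ])[1L]] <- 1
            if (any(!anyZero)) {
                w <- (1 / d[!anyZero, , drop = FALSE])^expo
                u[!anyZero, ] <- w / rowSums(w)
            }
            um <- u^m
            J <- sum(um * d)
            obj <- c(obj, J)
            if (is.finite(prev) && abs(prev - J) < tol) break
            prev <- J
            centers <- crossprod(um, x) / colSums(um)
        }
        list(centers = centers, u = u, obj = obj)
    }

    withSeed(seed, {
        best <- NULL
        for (s in seq_len(max(1L, nStart))) {
            fit <- runOnce()
            if (is.null(best) ||
                fit$obj[length(fit$obj)] < best$obj[length(best$obj)])
                best <- fit
        }
        dimnames(best$centers) <- list(NULL, colnames(x))
        rownames(best$u) <- rownames(x)
        new("FuzzyClusterModel", centroids = best$centers,
            membership = best$u, m = m, objective = best$obj,
            seed = as.integer(seed))
    })
}

#' Hard assignments and cluster prevalence
#'
#' Assigns each exon to the cluster of maximal membership (ties broken by
#' the lowest cluster index) and reports each cluster's prevalence as the
#' percentage of all clustered exons.
#'
#' @param model a [FuzzyClusterModel-class].
#' @return A list with `assignments` (named integer vector) and
#'   `prevalence` (numeric, percent per cluster, summing to 100).
#' @export
clusterAssignments <- function(model) {
    u <- memberships(model)
    hard <- max.col(u, ties.method = "first")
    names(hard) <- rownames(u)
    k <- ncol(u)
    prev <- 100 * tabulate(hard, nbins = k) / length(hard)
    names(prev) <- paste0("cluster", seq_len(k))
    list(assignments = hard, prevalence = prev)
}

#' Match clusters across cohorts by centroid shape
#'
#' Greedy minimal-Euclidean-distance matching of two models' centroids:
#' repeatedly pairs the globally closest unmatched centroids; pairs with
#' distance above `threshold` are reported unmatched (cohort-specific).
#'
#' @param modelA,modelB [FuzzyClusterModel-class] objects sharing the
#'   time-point dimension.
#' @param threshold maximum Euclidean distance for a match (default Inf).
#' @return A data.frame with columns `clusterA`, `clusterB` (NA when
#'   unmatched), `distance`.
#' @export
matchClusters <- function(modelA, modelB, threshold = Inf) {
    ca <- centroids(modelA)
    cb <- centroids(modelB)
    stopifnot(ncol(ca) == ncol(cb))
    d <- sqrt(pmax(sqDist(ca, cb), 0))
    pairs <- data.frame(clusterA = seq_len(nrow(ca)),
                        clusterB = NA_integer_,
                        distance = NA_real_)
    dm <- d
    for (step in seq_len(min(nrow(ca), nrow(cb)))) {
        if (all(!is.finite(dm))) break
        ij <- which(dm == min(dm, na.rm = TRUE), arr.ind = TRUE)[1L, ]
        if (dm[ij[1L], ij[2L]] > threshold) break
        pairs$clusterB[ij[1L]] <- ij[2L]
        pairs$distance[ij[1L]] <- d[ij[1L], ij[2L]]
        dm[ij[1L], ] <- Inf
        dm[, ij[2L]] <- Inf
    }
    pairs
}
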