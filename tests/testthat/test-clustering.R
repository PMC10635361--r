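test_that("cluster input is the union of significant exons", {
    r1 <- DataFrame(exon_id = sprintf("e%02d", 1:20),
                    significant = c(rep(TRUE, 10), rep(FALSE, 10)))
    r2 <- DataFrame(exon_id = sprintf("e%02d", 11:40),
                    significant = c(rep(TRUE, 15), rep(FALSE, 15)))
    ids <- selectClusterInput(list(r1, r2))
    expect_length(ids, 25L)
    expect_true("e11" %in% ids)          # significant only in the second
    expect_false("e40" %in% ids)         # significant in neither
})

test_that("center/scale standardizes rows and drops constants", {
    x <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(1, 0, 2))
    expect_warning(s <- centerScale(x), "constant")
    expect_equal(s["a", ], c(-1, 0, 1))
    expect_equal(attr(s, "dropped"), "b")
    expect_true(all(abs(rowMeans(s)) < 1e-10))
    expect_equal(unname(apply(s, 1, sd)), rep(1, 2))
})

test_that("k = 1 returns the mean with full membership", {
    set.seed(2)
    x <- matrix(rnorm(60), 20)
    m <- fuzzyCMeans(x, k = 1, seed = 1)
    expect_equal(as.numeric(centroids(m)), colMeans(x), tolerance = 1e-6)
    expect_equal(as.numeric(memberships(m)), rep(1, 20))
})

test_that("well-separated clouds are recovered exactly", {
    set.seed(3)
    x <- rbind(matrix(rnorm(150, 0, 0.1), 50),
               matrix(rnorm(150, 10, 0.1), 50))
    m <- fuzzyCMeans(x, k = 2, seed = 4)
    hard <- clusterAssignments(m)$assignments
    expect_equal(length(unique(hard[1:50])), 1L)
    expect_equal(length(unique(hard[51:100])), 1L)
    expect_false(hard[1] == hard[51])
})

test_that("memberships are a simplex and the objective never increases", {
    set.seed(5)
    for (rep in 1:5) {
        x <- matrix(rnorm(120), 40)
        m <- fuzzyCMeans(x, k = sample(2:5, 1), seed = rep)
        u <- memberships(m)
        expect_true(all(u >= 0 & u <= 1))
        expect_lt(max(abs(rowSums(u) - 1)), 1e-8)
        expect_true(all(diff(m@objective) <= 1e-9))
    }
    expect_error(fuzzyCMeans(matrix(rnorm(6), 2), k = 5, seed = 1),
                 "distinct")
    expect_error(fuzzyCMeans(matrix(rnorm(30), 10), k = 2, m = 1,
                             seed = 1), "m must be")
})

test_that("clustering agrees with the e1071 reference on one dataset", {
    skip_if_not_installed("e1071")
    tt <- templateTrajectories(50, sd = 0.3, seed = 17)
    ours <- clusterAssignments(fuzzyCMeans(tt$x, k = 6, seed = 1))
    set.seed(1)
    ref <- e1071::cmeans(tt$x, centers = 6, m = 2)
    # same partition up to label permutation
    expect_gt(matchedAccuracy(ref$cluster, ours$assignments), 0.9)
})

test_that("assignments break ties low and prevalences sum to 100", {
    u <- rbind(c(0.7, 0.1, 0.2), c(0.5, 0.5, 0), c(1 / 3, 1 / 3, 1 / 3))
    u <- u / rowSums(u)
    m <- methods::new("FuzzyClusterModel",
                      centroids = matrix(0, 3, 3),
                      membership = u, m = 2, objective = c(2, 1),
                      seed = 1L)
    a <- clusterAssignments(m)
    expect_equal(unname(a$assignments), c(1L, 1L, 1L))
    expect_equal(sum(a$prevalence), 100, tolerance = 1e-6)
})

test_that("standardization makes memberships affine-invariant", {
    tt <- templateTrajectories(20, sd = 0.3, seed = 23)
    raw <- 5 * tt$x + 3                  # common affine rescaling
    again <- centerScale(raw)
    expect_equal(unname(again), unname(tt$x), tolerance = 1e-12)
    m1 <- fuzzyCMeans(tt$x, k = 3, seed = 9)
    m2 <- fuzzyCMeans(again, k = 3, seed = 9)
    expect_equal(memberships(m1), memberships(m2), tolerance = 1e-10)
})

test_that("near-crisp fuzzifier reproduces k-means assignments", {
    set.seed(31)
    x <- matrix(rnorm(150), 50, 3)
    x[1:20, 1] <- x[1:20, 1] + 4
    x[21:35, 2] <- x[21:35, 2] + 4
    m <- fuzzyCMeans(x, k = 3, m = 1.05, seed = 7)
    hard <- clusterAssignments(m)$assignments
    km <- stats::kmeans(x, centers = centroids(m), iter.max = 100)
    expect_gt(mean(hard == km$cluster), 0.95)
})

test_that("centroid matching recovers permutations, flags orphans", {
    tt <- templateTrajectories(30, sd = 0.2, seed = 41)
    mA <- fuzzyCMeans(tt$x, k = 6, seed = 2)
    # identical centroid sets match identically
    self <- matchClusters(mA, mA)
    expect_equal(self$clusterB, self$clusterA)
    expect_true(all(self$distance < 1e-5))
    # a permuted copy is recovered; verify against all 6! matchings
    perm <- c(3, 1, 6, 2, 5, 4)
    mB <- methods::new("FuzzyClusterModel",
                       centroids = centroids(mA)[perm, ],
                       membership = memberships(mA)[, perm],
                       m = 2, objective = mA@objective, seed = 1L)
    got <- matchClusters(mA, mB)
    expect_equal(order(perm), got$clusterB)
    allPerms <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in allPerms(v[-i])) out <- c(out, list(c(v[i], p)))
        out
    }
    costs <- vapply(allPerms(1:6), function(p)
        sum(sqrt(rowSums((centroids(mA) -
                          centroids(mB)[p, ])^2))), numeric(1))
    best <- allPerms(1:6)[[which.min(costs)]]
    expect_equal(got$clusterB, best)
    # a centroid with no counterpart within threshold stays unmatched
    far <- methods::new("FuzzyClusterModel",
                        centroids = centroids(mA) + 100,
                        membership = memberships(mA),
                        m = 2, objective = mA@objective, seed = 1L)
    unm <- matchClusters(mA, far, threshold = 1)
    expect_true(all(is.na(unm$clusterB)))
})
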