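test_that("lcb reduces to the mean for kappa or sigma zero", {
    p <- predictiveGaussian(c(-5, 0, 3), c(4, 1, 9))
    expect_equal(lcb(p, 1), c(-7, -1, 0))
    expect_equal(lcb(p, 0), predMean(p))
    tiny <- predictiveGaussian(c(1, 2), c(1e-12, 1e-12))
    expect_equal(lcb(tiny, 5), c(1, 2), tolerance = 1e-5)
    expect_error(lcb(p, -1), "non-negative")
    set.seed(1)
    for (i in 1:20) {
        mu <- rnorm(10); v <- exp(rnorm(10)); k <- runif(1, 0, 3)
        expect_equal(lcb(predictiveGaussian(mu, v), k), mu - k * sqrt(v),
                     tolerance = 1e-12)
    }
})

test_that("batch selection avoids seen candidates and breaks ties by index", {
    scores <- c(5, 1, 3, 1, 2, 4)
    seen <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
    expect_identical(selectBatch(scores, seen, 3L), c(4L, 5L, 3L))
    expect_identical(selectBatch(rep(0, 6), rep(FALSE, 6), 3L), 1:3)
    expect_false(2L %in% selectBatch(scores, seen, 5L))
    expect_error(selectBatch(scores, rep(TRUE, 6), 1L), "unseen")
    # perfect scores + greedy semantics: lowest objectives selected
    obj <- c(0.3, -2, 5, -1, 0)
    expect_identical(sort(selectBatch(obj, rep(FALSE, 5), 2L)), c(2L, 4L))
})

test_that("bo trajectories are monotone, reproducible and within budget", {
    set.seed(2)
    n <- 120
    lib <- candidateLibrary(sprintf("mol%03d", 1:n),
                            matrix(rnorm(n * 4), n), rnorm(n))
    surr <- function(ctx, X) {
        # simple nearest-mean surrogate: predict the mean of seen values
        predictiveGaussian(rep(mean(ctx$y), nrow(X)), rep(1, nrow(X)))
    }
    tr <- runBO(surr, lib, "lcb", batchSize = 5L, budget = 60L, nInit = 10L,
                seed = 4)
    expect_true(all(diff(bestSoFar(tr)) <= 0))
    expect_lte(length(tr@index), 60L)
    expect_lte(max(tr@iteration), ceiling((60 - 10) / 5))
    tr2 <- runBO(surr, lib, "lcb", batchSize = 5L, budget = 60L, nInit = 10L,
                 seed = 4)
    expect_identical(tr@index, tr2@index)
    expect_error(runBO(surr, lib, "lcb", budget = 200L, nInit = 10L),
                 "larger than the budget")
})

test_that("a perfect greedy predictor finds the optimum immediately", {
    set.seed(3)
    n <- 100
    obj <- rnorm(n)
    lib <- candidateLibrary(sprintf("m%03d", 1:n), matrix(rnorm(n * 3), n), obj)
    oracle <- function(ctx, X) predictiveGaussian(obj, rep(1e-6, n))
    tr <- runBO(oracle, lib, "greedy", batchSize = 5L, budget = 30L,
                nInit = 20L, seed = 5)
    firstBatch <- tr@index[tr@iteration == 1L]
    best <- which.min(obj)
    expect_true(best %in% tr@index[tr@iteration <= 1L])
    expect_equal(min(bestSoFar(tr)), min(obj))
    # the first post-init batch is exactly the top unseen candidates
    init <- tr@index[tr@iteration == 0L]
    unseenRank <- setdiff(order(obj), init)
    expect_setequal(firstBatch, unseenRank[1:5])
})

test_that("random acquisition picks unseen candidates uniformly", {
    set.seed(6)
    n <- 30
    lib <- candidateLibrary(sprintf("m%02d", 1:n), matrix(rnorm(n * 2), n),
                            rnorm(n))
    counts <- integer(n)
    for (s in 1:400) {
        tr <- runBO(NULL, lib, "random", batchSize = 2L, budget = 6L,
                    nInit = 2L, seed = s)
        counts[tr@index] <- counts[tr@index] + 1L
    }
    # 2400 draws over 30 candidates: chi-square uniformity sanity check
    chi <- sum((counts - mean(counts))^2 / mean(counts))
    expect_lt(chi, qchisq(0.999, df = n - 1))
})

test_that("task augmentation honours the grammar and the exclusion set", {
    set.seed(7)
    scores <- matrix(rnorm(40 * 4), 40,
                     dimnames = list(NULL, c("F2", "JAK2", "PARP1", "ESR2")))
    qed <- runif(40, 0.2, 0.9)
    aug <- augmentTasks(scores, qed, n = 200L, exclude = c("F2", "JAK2"),
                        seed = 8)
    expect_lte(length(aug), 200L)
    expect_gt(length(aug), 0L)
    for (a in aug) {
        expect_false(any(a$sources %in% c("F2", "JAK2")))
        expect_length(a$labels, 40L)
    }
    # with no exclusions the full count is returned
    aug2 <- augmentTasks(scores, qed, n = 50L, seed = 9)
    expect_length(aug2, 50L)
    expect_error(augmentTasks(scores, qed, 10L,
                              exclude = colnames(scores)), "covers all")
    # min-with-median on a fixed column
    col <- c(-10, -8, -6)
    expect_equal(pmin(col, stats::median(col)), c(-10, -8, -8))
})

test_that("tanimoto GP matches a brute-force exact-GP oracle", {
    set.seed(10)
    fps <- smilesToFingerprint(FIXTURE_SMILES, nBits = 256L, radius = 2L)
    X <- fpBits(fps)
    ytr <- rnorm(6)
    p <- tanimotoGpFitPredict(X[1:6, ], ytr, X[7:10, ], noise = 0.05)
    # oracle: direct matrix inversion with an independently computed kernel
    tk <- function(a, b) {
        i <- sum(a & b); u <- sum(a | b); if (u == 0) 1 else i / u
    }
    K <- outer(1:6, 1:6, Vectorize(function(i, j) tk(X[i, ], X[j, ])))
    Ks <- outer(7:10, 1:6, Vectorize(function(i, j) tk(X[i, ], X[j, ])))
    Kinv <- solve(K + diag(0.05, 6))
    expect_equal(predMean(p), as.numeric(Ks %*% Kinv %*% ytr),
                 tolerance = 1e-8)
    expect_equal(predVar(p),
                 pmax(1 - diag(Ks %*% Kinv %*% t(Ks)), 1e-12),
                 tolerance = 1e-8)
    # posterior variance never exceeds the prior k(x, x) = 1
    expect_true(all(predVar(p) <= 1))
    # near-interpolation at a training point as noise vanishes
    p0 <- tanimotoGpFitPredict(X[1:6, ], ytr, X[1, , drop = FALSE],
                               noise = 1e-8)
    expect_equal(predMean(p0)[1], ytr[1], tolerance = 1e-4)
})
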