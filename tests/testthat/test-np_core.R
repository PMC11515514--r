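test_that("context encoding is permutation invariant and mean aggregated", {
    set.seed(1)
    m <- tinyModel("CNP")
    ctx <- randomSet(7)
    r <- encodeContexts(m, ctx)$r
    expect_length(r, m@config$rDim)
    perm <- sample(7)
    expect_equal(encodeContexts(m, permuteSet(ctx, perm))$r, r,
                 tolerance = 1e-10)
    # duplicating every context leaves the mean aggregate unchanged
    dup <- contextSet(rbind(ctx$x, ctx$x), c(ctx$y, ctx$y))
    expect_equal(encodeContexts(m, dup)$r, r, tolerance = 1e-10)
    # empty context set encodes to the zero vector
    empty <- contextSet(matrix(numeric(0), 0, 2), numeric(0))
    expect_equal(encodeContexts(m, empty)$r, numeric(m@config$rDim))
})

test_that("prediction respects target order, positivity and determinism", {
    set.seed(2)
    m <- tinyModel("CNP")
    ctx <- randomSet(5)
    tx <- matrix(rnorm(12), 6)
    p <- npPredict(m, ctx, tx)
    expect_length(predMean(p), 6)
    expect_true(all(predVar(p) >= m@config$varianceFloor))
    perm <- sample(6)
    p2 <- npPredict(m, ctx, tx[perm, ])
    expect_equal(predMean(p2), predMean(p)[perm], tolerance = 1e-12)
    expect_identical(predMean(npPredict(m, ctx, tx)), predMean(p))
    # input-dimension mismatch is an error
    expect_error(npPredict(m, ctx, matrix(rnorm(9), 3)), "dimension")
})

test_that("log predictive density matches the closed-form Gaussian sum", {
    p <- predictiveGaussian(0, 1)
    expect_equal(logPredictiveDensity(p, 0), -0.5 * log(2 * pi),
                 tolerance = 1e-12)
    pT <- predictiveGaussian(rep(0, 7), rep(1, 7))
    expect_equal(logPredictiveDensity(pT, rep(0, 7)),
                 7 * logPredictiveDensity(p, 0), tolerance = 1e-12)
    # doubling the variance at mu = y loses log(2)/2 per point
    expect_equal(logPredictiveDensity(predictiveGaussian(1, 2), 1),
                 logPredictiveDensity(predictiveGaussian(1, 1), 1) - 0.5 * log(2),
                 tolerance = 1e-12)
    expect_error(logPredictiveDensity(p, c(0, 1)), "lengths differ")
})

test_that("cnp loss composes prediction and density and is invariant", {
    set.seed(3)
    m <- tinyModel("CNP")
    ctx <- randomSet(6); tgt <- randomSet(4)
    l <- cnpLoss(m, ctx, tgt)
    expect_equal(l, -logPredictiveDensity(npPredict(m, ctx, tgt$x), tgt$y),
                 tolerance = 1e-12)
    expect_equal(cnpLoss(m, permuteSet(ctx, sample(6)), tgt), l,
                 tolerance = 1e-10)
    # sigma2 <= 1/(2pi) everywhere makes every point's NLL non-negative
    small <- predictiveGaussian(rep(0, 3), rep(1 / (2 * pi) * 0.9, 3))
    expect_gte(-logPredictiveDensity(small, c(0, 0.1, -0.2)), 0)
})

test_that("latent posterior is a proper permutation-invariant Gaussian", {
    set.seed(4)
    m <- tinyModel("LNP")
    data <- randomSet(8)
    post <- lnpPosterior(m, data)
    expect_length(post$mean, m@config$zDim)
    expect_true(all(post$variance > 0))
    post2 <- lnpPosterior(m, permuteSet(data, sample(8)))
    expect_equal(post2$mean, post$mean, tolerance = 1e-10)
    expect_equal(post2$variance, post$variance, tolerance = 1e-10)
    # conditioning on more data changes the posterior deterministically
    more <- contextSet(rbind(data$x, matrix(rnorm(4), 2)), c(data$y, rnorm(2)))
    pm1 <- lnpPosterior(m, more); pm2 <- lnpPosterior(m, more)
    expect_identical(pm1, pm2)
    expect_false(isTRUE(all.equal(pm1$mean, post$mean)))
})

test_that("KL helper matches the closed form", {
    expect_equal(klDiagGaussian(1, 1, 0, 1), 0.5, tolerance = 1e-12)
    expect_equal(klDiagGaussian(0, 1, 0, 1), 0, tolerance = 1e-12)
    expect_equal(klDiagGaussian(c(1, 0), c(1, 1), c(0, 0), c(1, 1)), 0.5,
                 tolerance = 1e-12)
    # against direct numeric formula on random moments
    set.seed(5)
    for (i in 1:10) {
        m1 <- rnorm(3); v1 <- exp(rnorm(3)); m0 <- rnorm(3); v0 <- exp(rnorm(3))
        direct <- sum(0.5 * (log(v0) - log(v1) + (v1 + (m1 - m0)^2) / v0 - 1))
        expect_equal(klDiagGaussian(m1, v1, m0, v0), direct, tolerance = 1e-12)
    }
})

test_that("lnp loss is reproducible and its KL term vanishes when equal", {
    set.seed(6)
    m <- tinyModel("LNP")
    ctx <- randomSet(6); tgt <- randomSet(4)
    l1 <- lnpLoss(m, ctx, tgt, seed = 11)
    expect_identical(lnpLoss(m, ctx, tgt, seed = 11), l1)
    expect_false(identical(lnpLoss(m, ctx, tgt, seed = 12), l1))
    expect_equal(lnpLoss(m, permuteSet(ctx, sample(6)), tgt, seed = 11), l1,
                 tolerance = 1e-8)
})

test_that("analytic gradients match finite differences for both model kinds", {
    set.seed(7)
    ctx <- list(randomSet(4), randomSet(3))
    tgt <- list(randomSet(5), randomSet(2))
    batch <- molnp:::.makeBatch(ctx, tgt)
    for (kind in c("CNP", "LNP")) {
        m <- tinyModel(kind, seed = 3)
        eps <- if (kind == "LNP") matrix(rnorm(2 * m@config$zDim), 2) else NULL
        lossFn <- function(mo)
            molnp:::.npBatchLossGrad(mo, batch, wantGrads = FALSE, eps = eps)$loss
        ana <- molnp:::.npBatchLossGrad(m, batch, wantGrads = TRUE, eps = eps)$grads
        checked <- 0L
        for (g in names(m@layers)) for (l in seq_along(m@layers[[g]])) {
            coords <- sample(length(m@layers[[g]][[l]]$W), 3)
            num <- numGrad(lossFn, m, g, l, "W", coords)
            ok <- !is.na(num)   # drop stencils that straddle a ReLU kink
            expect_equal(num[ok], ana[[g]][[l]]$W[coords][ok],
                         tolerance = 1e-4)
            bc <- sample(length(m@layers[[g]][[l]]$b), 2)
            numB <- numGrad(lossFn, m, g, l, "b", bc)
            okB <- !is.na(numB)
            expect_equal(numB[okB], ana[[g]][[l]]$b[bc][okB],
                         tolerance = 1e-4)
            checked <- checked + sum(ok) + sum(okB)
        }
        expect_gt(checked, 20L)   # most coordinates must actually be compared
    }
})

test_that("prediction stays finite with variance floor on extreme inputs", {
    m <- tinyModel("CNP")
    ctx <- contextSet(matrix(c(1e4, -1e4, 50, -50), 2), c(1e3, -1e3))
    p <- npPredict(m, ctx, matrix(c(1e4, -1e4), 1))
    expect_true(all(is.finite(predMean(p))))
    expect_true(all(predVar(p) >= m@config$varianceFloor))
})

test_that("checkpoints round-trip weights bit-stably", {
    m <- npModel("LNP", dimX = 3, hidden = 16, rDim = 8, zDim = 4, seed = 9,
                 featurizer = list(nBits = 512L, radius = 2L))
    path <- tempfile(fileext = ".rds")
    saveNPModel(m, path)
    m2 <- loadNPModel(path)
    expect_identical(m2@layers, m@layers)
    expect_identical(m2@config, m@config)
    expect_identical(m2@kind, m@kind)
})

test_that("trained CNP approaches the exact Bayes posterior on linear tasks", {
    # tasks: y = w x + eps with w ~ N(0, 1), eps ~ N(0, 0.25). The exact
    # posterior mean at x* given contexts is x* * (sum xy) / (sum x^2 + s2/t2)
    set.seed(10)
    s2 <- 0.25
    makeTask <- function(n = 40) {
        w <- rnorm(1)
        x <- runif(n, -2, 2)
        taskObservations(x, w * x + rnorm(n, sd = sqrt(s2)))
    }
    tasks <- lapply(1:150, function(i) makeTask())
    m <- npModel("CNP", dimX = 1, hidden = 32, rDim = 32, seed = 2)
    cfg <- samplingConfig(cRange = c(5L, 15L), tRange = c(5L, 15L))
    trained <- metaTrain(m, tasks, cfg, epochs = 80, seed = 3)$model
    gap <- function(model) {
        set.seed(77)
        mean(replicate(30, {
            tk <- makeTask()
            sp <- sampleSplit(tk, samplingConfig(cRange = c(8L, 9L),
                                                 tRange = c(20L, 21L)))
            xs <- sp$contexts$x[, 1]; ys <- sp$contexts$y
            wBar <- sum(xs * ys) / (sum(xs^2) + s2)
            bayes <- wBar * sp$targets$x[, 1]
            p <- npPredict(model, sp$contexts, sp$targets$x)
            sqrt(mean((predMean(p) - bayes)^2))
        }))
    }
    expect_lt(gap(trained), gap(m))      # training shrinks the gap ...
    expect_lt(gap(trained), 0.35)        # ... to near the closed-form oracle
})
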