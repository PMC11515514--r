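# Desk-scale experiment drivers. Each driver runs one seed of a study on
# synthetic data (generation, meta-training, evaluation) and returns the
# measured quantities; callers loop over seeds and take medians. Problem
# sizes default to the package's desk-scale study conditions (documented in
# the methods vignette).

.deriveSeed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2147483L

#' Sinusoid meta-generalization and fine-tuning recovery experiment
#'
#' Meta-trains a CNP on sinusoid tasks of frequency rho = 1, then measures
#' held-out mean target MSE on fresh rho = 1 tasks (against the
#' task-variance baseline of predicting each task's mean) and on
#' frequency-shifted rho = 1.5 tasks — the meta-generalization stress test.
#' Optionally fine-tunes on each shifted task's contexts (last two decoder
#' layers) and records the MSE before and after adaptation.
#'
#' @param seed experiment seed.
#' @param nTasks meta-training tasks (default 500).
#' @param nPoints observations per task (default 100).
#' @param epochs meta-training epochs (default 300).
#' @param hidden,rDim network widths (default 64).
#' @param rhoShift shifted test frequency (default 1.5).
#' @param nEvalTasks held-out tasks per evaluation (default 50).
#' @param nContexts contexts per evaluation task (default 20).
#' @param nFtContexts contexts per fine-tuning task (default 100).
#' @param finetune also run the fine-tuning recovery arm?
#' @param ftConfig fine-tuning configuration.
#' @return list with \code{model}, \code{mseBase} (rho = 1 MSE),
#'   \code{mseShift} (rho = 1.5 MSE), \code{baselineVar} (mean task
#'   variance), and when fine-tuning: \code{mseShiftBefore},
#'   \code{mseShiftAfter} on the adaptation tasks.
#' @export
runSinusoidExperiment <- function(seed = 1L, nTasks = 500L, nPoints = 100L,
                                  epochs = 300L, hidden = 64L, rDim = 64L,
                                  rhoShift = 1.5, nEvalTasks = 50L,
                                  nContexts = 20L, nFtContexts = 100L,
                                  finetune = TRUE,
                                  ftConfig = fineTuneConfig()) {
    set.seed(.deriveSeed(seed, 1L))
    fam <- sinusoidFamily()
    tasks <- lapply(seq_len(nTasks), function(i) sampleSinusoidTask(fam, nPoints))
    model <- npModel("CNP", dimX = 1L, hidden = hidden, rDim = rDim,
                     seed = .deriveSeed(seed, 2L))
    cfg <- samplingConfig(cRange = c(10L, 48L), tRange = c(10L, 48L))
    model <- metaTrain(model, tasks, cfg, epochs = epochs,
                       seed = .deriveSeed(seed, 3L))$model

    evalTasks <- function(rho, nC, k) {
        set.seed(.deriveSeed(seed, k))
        f <- sinusoidFamily(rho = rho)
        lapply(seq_len(nEvalTasks), function(i) {
            tk <- sampleSinusoidTask(f, nPoints)
            sampleSplit(tk, samplingConfig(cRange = c(nC, nC + 1L),
                                           tRange = c(50L, 51L)))
        })
    }
    mseOf <- function(m, sp) {
        p <- npPredict(m, sp$contexts, sp$targets$x)
        mean((predMean(p) - sp$targets$y)^2)
    }
    base <- evalTasks(1, nContexts, 4L)
    shift <- evalTasks(rhoShift, nContexts, 5L)
    out <- list(model = model,
                mseBase = mean(vapply(base, mseOf, numeric(1), m = model)),
                mseShift = mean(vapply(shift, mseOf, numeric(1), m = model)),
                baselineVar = mean(vapply(base, function(sp)
                    mean((sp$targets$y - mean(sp$targets$y))^2), numeric(1))))
    if (finetune) {
        ft <- evalTasks(rhoShift, nFtContexts, 6L)
        before <- after <- numeric(length(ft))
        for (i in seq_along(ft)) {
            before[i] <- mseOf(model, ft[[i]])
            adapted <- fineTune(model, ft[[i]]$contexts, ftConfig,
                                seed = .deriveSeed(seed, 100L + i))
            after[i] <- mseOf(adapted, ft[[i]])
        }
        out$mseShiftBefore <- mean(before)
        out$mseShiftAfter <- mean(after)
    }
    out
}

# shared builder: synthetic molecular meta-dataset split into meta-train /
# meta-test tasks over a generated SMILES library
.molMetaData <- function(seed, nMolecules, nTasks, nTestTasks, lambda,
                         nBits = 512L, noiseSd = 0.3) {
    smiles <- generateSmilesLibrary(nMolecules, seed = .deriveSeed(seed, 11L))
    spec <- synthMolTaskSpec(nTasks = nTasks, lambda = lambda, nBits = nBits,
                             noiseSd = noiseSd, seed = .deriveSeed(seed, 12L))
    md <- makeMolecularMetadataset(smiles, spec)
    idxTest <- seq_len(nTestTasks)
    list(md = md, trainTasks = md$tasks[-idxTest], testTasks = md$tasks[idxTest])
}

#' Calibration experiment on a synthetic molecular meta-dataset
#'
#' Meta-trains a CNP on correlated synthetic molecular tasks, predicts
#' held-out meta-test tasks from a fixed number of contexts, pools targets
#' across test tasks, and computes the calibration correlation (Pearson of
#' log mean MSE vs log mean predicted variance across confidence
#' percentiles), before and optionally after per-task fine-tuning.
#'
#' @param seed experiment seed.
#' @param nMolecules library size (default 500).
#' @param nTasks total tasks (default 50).
#' @param nTestTasks meta-test tasks held out (default 10).
#' @param lambda inter-task correlation control (default 0.7).
#' @param nBits fingerprint length for the experiment (default 512).
#' @param epochs meta-training epochs (default 60).
#' @param hidden,rDim network widths (defaults 128 / 64).
#' @param nContexts contexts per test task (default 200).
#' @param nGroups confidence percentiles (default 20).
#' @param finetune also evaluate after fine-tuning?
#' @return list with \code{corBefore}, \code{corAfter} (NA when finetune =
#'   FALSE), \code{nlpdBefore}, \code{nlpdAfter}, and the percentile
#'   summaries.
#' @export
runCalibrationExperiment <- function(seed = 1L, nMolecules = 500L,
                                     nTasks = 50L, nTestTasks = 10L,
                                     lambda = 0.7, nBits = 512L,
                                     epochs = 60L, hidden = 128L, rDim = 64L,
                                     nContexts = 200L, nGroups = 20L,
                                     finetune = TRUE) {
    dat <- .molMetaData(seed, nMolecules, nTasks, nTestTasks, lambda, nBits)
    model <- npModel("CNP", dimX = nBits, hidden = hidden, rDim = rDim,
                     seed = .deriveSeed(seed, 13L))
    model <- metaTrain(model, dat$trainTasks, samplingConfig(),
                       epochs = epochs, seed = .deriveSeed(seed, 14L))$model

    evalTask <- function(m, tk, ctxIdx) {
        x <- taskX(tk); y <- taskY(tk)
        tIdx <- setdiff(seq_len(nObs(tk)), ctxIdx)
        p <- npPredict(m, contextSet(x[ctxIdx, , drop = FALSE], y[ctxIdx]),
                       x[tIdx, , drop = FALSE])
        list(pred = p, y = y[tIdx])
    }
    set.seed(.deriveSeed(seed, 15L))
    ctxIdx <- lapply(dat$testTasks, function(tk) sample.int(nObs(tk), nContexts))
    pool <- function(m, finetuned = FALSE) {
        mu <- v <- yy <- numeric(0)
        for (i in seq_along(dat$testTasks)) {
            tk <- dat$testTasks[[i]]
            mi <- m
            if (finetuned) {
                ctx <- contextSet(taskX(tk)[ctxIdx[[i]], , drop = FALSE],
                                  taskY(tk)[ctxIdx[[i]]])
                mi <- fineTune(m, ctx, fineTuneConfig(),
                               seed = .deriveSeed(seed, 200L + i))
            }
            e <- evalTask(mi, tk, ctxIdx[[i]])
            mu <- c(mu, predMean(e$pred)); v <- c(v, predVar(e$pred))
            yy <- c(yy, e$y)
        }
        pred <- predictiveGaussian(mu, v)
        ps <- confidencePercentiles(pred, yy, nGroups)
        list(cor = calibrationCorrelation(ps), nlpd = nlpd(pred, yy),
             percentiles = ps)
    }
    before <- pool(model, FALSE)
    out <- list(model = model, corBefore = before$cor,
                nlpdBefore = before$nlpd, percentilesBefore = before$percentiles,
                corAfter = NA_real_, nlpdAfter = NA_real_)
    if (finetune) {
        after <- pool(model, TRUE)
        out$corAfter <- after$cor
        out$nlpdAfter <- after$nlpd
        out$percentilesAfter <- after$percentiles
    }
    out
}

#' Context/target-fraction overfitting sweep
#'
#' Trains the same architecture on the same synthetic molecular
#' meta-dataset for the same number of epochs under different
#' context/target fractions f (with overlapping sets, so f can reach 1)
#' and measures the meta-test NLPD. Large fractions multiply the effective
#' epochs and destroy calibration on held-out tasks.
#'
#' @param seed experiment seed.
#' @param fractions fractions to sweep (default c(0.05, 1)).
#' @param nMolecules,nTasks,nTestTasks,lambda,nBits dataset conditions
#'   (defaults 150 / 25 / 10 / 0.7 / 256; sized so that both arms train to
#'   convergence, where the fraction — not the step count — separates them).
#' @param epochs training epochs per arm (default 300).
#' @param hidden,rDim network widths (defaults 128 / 64).
#' @param nContexts contexts per test task at evaluation (default 50).
#' @param nCtxDraws independent context draws averaged per evaluation task
#'   (default 3; reduces measurement noise in the NLPD estimate).
#' @return data frame with columns \code{fraction}, \code{testNLPD},
#'   \code{trainNLPD} (NLPD on held-in tasks' held-out role as targets).
#' @export
runOverfitSweep <- function(seed = 1L, fractions = c(0.05, 1),
                            nMolecules = 150L, nTasks = 25L, nTestTasks = 10L,
                            lambda = 0.7, nBits = 256L, epochs = 300L,
                            hidden = 128L, rDim = 64L, nContexts = 50L,
                            nCtxDraws = 3L) {
    dat <- .molMetaData(seed, nMolecules, nTasks, nTestTasks, lambda, nBits)
    drawIdx <- function(tasks, k) {
        set.seed(.deriveSeed(seed, k))
        lapply(tasks, function(tk)
            lapply(seq_len(nCtxDraws), function(d) sample.int(nObs(tk), nContexts)))
    }
    ctxIdx <- drawIdx(dat$testTasks, 15L)
    nTrainEval <- min(5L, length(dat$trainTasks))
    trainIdx <- drawIdx(dat$trainTasks[seq_len(nTrainEval)], 16L)
    res <- lapply(fractions, function(f) {
        cfg <- samplingConfig(fraction = f, allowOverlap = TRUE)
        model <- npModel("CNP", dimX = nBits, hidden = hidden, rDim = rDim,
                         seed = .deriveSeed(seed, 13L))
        model <- metaTrain(model, dat$trainTasks, cfg, epochs = epochs,
                           seed = .deriveSeed(seed, 14L))$model
        nl <- function(tasks, idxList) {
            mean(mapply(function(tk, draws) {
                x <- taskX(tk); y <- taskY(tk)
                mean(vapply(draws, function(ci) {
                    ti <- setdiff(seq_len(nObs(tk)), ci)
                    p <- npPredict(model,
                                   contextSet(x[ci, , drop = FALSE], y[ci]),
                                   x[ti, , drop = FALSE])
                    nlpd(p, y[ti])
                }, numeric(1)))
            }, tasks, idxList))
        }
        data.frame(fraction = f,
                   testNLPD = nl(dat$testTasks, ctxIdx),
                   trainNLPD = nl(dat$trainTasks[seq_len(nTrainEval)], trainIdx))
    })
    do.call(rbind, res)
}

#' Bayesian-optimization experiment on a synthetic molecular library
#'
#' Builds a candidate library whose hidden objective is one task of a
#' correlated synthetic molecular task family, meta-trains a CNP on the
#' remaining tasks, and runs batched BO with greedy, LCB and random
#' acquisition (plus optionally a Tanimoto-kernel GP surrogate), recording
#' the final best objective value per strategy.
#'
#' @param seed experiment seed.
#' @param nLibrary library size (default 2000).
#' @param nTasks meta-training tasks (default 30).
#' @param lambda inter-task correlation (default 0.7).
#' @param nBits fingerprint length (default 512).
#' @param epochs meta-training epochs (default 40).
#' @param hidden,rDim network widths (defaults 128 / 64).
#' @param budget,batchSize,nInit BO settings (defaults 200 / 5 / 20).
#' @param kappa LCB weight (default 1).
#' @param gp also run the Tanimoto-GP-LCB arm (default TRUE)?
#' @return list with the \code{library}, per-strategy trajectories
#'   (\code{greedy}, \code{lcb}, \code{random}, optionally \code{gp}), the
#'   library optimum \code{best}, and \code{finalBest} (named vector of
#'   final best-so-far values).
#' @export
runBOExperiment <- function(seed = 1L, nLibrary = 2000L, nTasks = 30L,
                            lambda = 0.7, nBits = 512L, epochs = 40L,
                            hidden = 128L, rDim = 64L, budget = 200L,
                            batchSize = 5L, nInit = 20L, kappa = 1,
                            gp = TRUE) {
    dat <- .molMetaData(seed, nLibrary, nTasks + 1L, 1L, lambda, nBits)
    objective <- taskY(dat$testTasks[[1]])
    lib <- candidateLibrary(generateSmilesLibrary(nLibrary,
                                                  seed = .deriveSeed(seed, 11L)),
                            taskX(dat$testTasks[[1]]), objective)
    model <- npModel("CNP", dimX = nBits, hidden = hidden, rDim = rDim,
                     seed = .deriveSeed(seed, 13L))
    model <- metaTrain(model, dat$trainTasks, samplingConfig(),
                       epochs = epochs, seed = .deriveSeed(seed, 14L))$model
    npSurrogate <- function(ctx, X) chunkedPredict(model, ctx, X, 4096L)
    run <- function(acq, surr) runBO(surr, lib, acq, batchSize = batchSize,
                                     budget = budget, kappa = kappa,
                                     nInit = nInit,
                                     seed = .deriveSeed(seed, 21L))
    out <- list(library = lib, best = min(objective),
                greedy = run("greedy", npSurrogate),
                lcb = run("lcb", npSurrogate),
                random = run("random", NULL))
    if (gp) {
        gpSurrogate <- function(ctx, X)
            tanimotoGpFitPredict(ctx$x, ctx$y, X, noise = 0.1)
        out$gp <- run("lcb", gpSurrogate)
    }
    fb <- vapply(out[intersect(c("greedy", "lcb", "random", "gp"), names(out))],
                 function(tr) min(bestSoFar(tr)), numeric(1))
    out$finalBest <- fb
    out
}
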