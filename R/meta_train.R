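# Randomized context/target splitting, the meta-training loop, effective
# epoch accounting and the chunked prediction memory contract.

#' Sampling configuration for meta-training splits
#'
#' At every visit of a task, context and target sizes are drawn uniformly
#' from half-open integer intervals (default [20, 150), the randomization
#' that keeps effective epochs low and drives calibration), and disjoint
#' index sets of those sizes are subsampled from the task's observations
#' with C + T <= O_i. \code{fraction} switches to fraction mode (the
#' overfitting sweep): C = T = round(f * O_i), optionally with overlapping
#' context/target sets so f can reach 1.
#'
#' @param cRange,tRange half-open integer intervals [lo, hi) for context and
#'   target sizes.
#' @param disjoint enforce disjoint context and target index sets.
#' @param fraction optional fraction f in (0, 1] of observations used as
#'   contexts and as targets, overriding the ranges.
#' @param allowOverlap allow context and target sets to overlap (required
#'   for fraction > 0.5).
#' @return a list of class \code{"samplingConfig"}.
#' @export
samplingConfig <- function(cRange = c(20L, 150L), tRange = c(20L, 150L),
                           disjoint = TRUE, fraction = NULL,
                           allowOverlap = FALSE) {
    if (length(cRange) != 2L || cRange[2] <= cRange[1] || cRange[1] < 1L)
        stop("cRange must be a nonempty integer interval [lo, hi)")
    if (length(tRange) != 2L || tRange[2] <= tRange[1] || tRange[1] < 1L)
        stop("tRange must be a nonempty integer interval [lo, hi)")
    if (!is.null(fraction) && (fraction <= 0 || fraction > 1))
        stop("fraction must lie in (0, 1]")
    structure(list(cRange = as.integer(cRange), tRange = as.integer(tRange),
                   disjoint = disjoint, fraction = fraction,
                   allowOverlap = allowOverlap),
              class = "samplingConfig")
}

.drawSize <- function(range) {
    if (range[2] - range[1] <= 1L) return(range[1])
    range[1] + sample.int(range[2] - range[1], 1L) - 1L
}

#' Draw a random context/target split from a task
#'
#' Context and target sizes are drawn uniformly from the configured ranges
#' and disjoint index subsets of the task's observations are sampled, with
#' C + T <= O_i. Tasks smaller than the minimum requested sizes are handled
#' by rescaling both ranges proportionally (each size kept >= 1). In
#' fraction mode, C = T = round(f * O_i); with \code{allowOverlap} the two
#' index sets are drawn independently and disjointness is not enforced.
#'
#' @param task a \linkS4class{TaskObservations}.
#' @param config a \code{\link{samplingConfig}}.
#' @return list with labelled \code{contexts} and \code{targets}
#'   (\code{\link{contextSet}}s) and the index vectors used.
#' @export
sampleSplit <- function(task, config = samplingConfig()) {
    stopifnot(is(task, "TaskObservations"))
    O <- nObs(task)
    if (O < 2L) stop("a task needs at least 2 observations to split")
    if (!is.null(config$fraction)) {
        n <- max(1L, as.integer(round(config$fraction * O)))
        if (config$allowOverlap) {
            ci <- sample.int(O, n)
            ti <- sample.int(O, n)
        } else {
            if (2L * n > O) stop("fraction > 0.5 requires allowOverlap = TRUE")
            idx <- sample.int(O, 2L * n)
            ci <- idx[seq_len(n)]; ti <- idx[n + seq_len(n)]
        }
    } else {
        cR <- config$cRange; tR <- config$tRange
        minSum <- cR[1] + tR[1]
        if (O < minSum) {  # small-task rescue: shrink both ranges
            s <- O / minSum
            cR <- pmax(1L, as.integer(floor(cR * s)))
            tR <- pmax(1L, as.integer(floor(tR * s)))
            if (cR[2] <= cR[1]) cR[2] <- cR[1] + 1L
            if (tR[2] <= tR[1]) tR[2] <- tR[1] + 1L
        }
        Cn <- .drawSize(c(cR[1], min(cR[2], O - tR[1] + 1L)))
        Tn <- .drawSize(c(tR[1], min(tR[2], O - Cn + 1L)))
        if (config$disjoint && !config$allowOverlap) {
            idx <- sample.int(O, Cn + Tn)
            ci <- idx[seq_len(Cn)]; ti <- idx[Cn + seq_len(Tn)]
        } else {
            ci <- sample.int(O, Cn)
            ti <- sample.int(O, Tn)
        }
    }
    x <- taskX(task); y <- taskY(task)
    list(contexts = contextSet(x[ci, , drop = FALSE], y[ci]),
         targets = contextSet(x[ti, , drop = FALSE], y[ti]),
         contextIdx = ci, targetIdx = ti)
}

#' Effective epochs
#'
#' The average number of times an observed datapoint is seen during
#' training: \code{e * nBar / O}, where \code{e} is the number of epochs,
#' \code{nBar} the average number of points sampled from the task per epoch
#' (counting views as context and as target), and \code{O} the task's total
#' number of observations.
#'
#' @param e epochs run (>= 0).
#' @param nBar average sample size per epoch.
#' @param O number of observations of the task (>= 1).
#' @return effective epochs (numeric).
#' @export
effectiveEpochs <- function(e, nBar, O) {
    if (O < 1) stop("O must be at least 1")
    if (e < 0) stop("e must be non-negative")
    e * nBar / O
}

#' Meta-train a neural process
#'
#' Optimizes the Monte-Carlo estimate of the meta-training objective: each
#' epoch visits every task once in a random order; for every task a fresh
#' random context/target split is drawn; per-task losses (CNP negative
#' predictive log-likelihood, or the LNP variational objective) are averaged
#' over the tasks of a mini-batch and one Adam step is taken per mini-batch.
#'
#' @param model an \linkS4class{NPModel}.
#' @param tasks list of \linkS4class{TaskObservations}.
#' @param config a \code{\link{samplingConfig}}.
#' @param epochs number of epochs (>= 1).
#' @param batchSize tasks per mini-batch (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param clip gradient-norm clip (default 10).
#' @param seed RNG seed controlling splits, batching and latent samples.
#' @param splitsPerVisit Monte-Carlo split draws per task visit (default 1).
#' @return list with the trained \code{model} and a \code{report} data frame
#'   (epoch, mean objective) plus the seed and a config snapshot as
#'   attributes.
#' @export
metaTrain <- function(model, tasks, config = samplingConfig(), epochs = 10L,
                      batchSize = 16L, lr = 1e-3, clip = 10, seed = 1L,
                      splitsPerVisit = 1L) {
    stopifnot(is(model, "NPModel"), length(tasks) >= 1L, epochs >= 1L)
    set.seed(seed)
    layers <- model@layers
    state <- .adamInit(layers)
    n <- length(tasks)
    objective <- numeric(epochs)
    t <- 0L
    for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        epLoss <- 0; nBatches <- 0L
        for (start in seq(1L, n, by = batchSize)) {
            ids <- ord[start:min(start + batchSize - 1L, n)]
            bloss <- 0
            for (rep in seq_len(splitsPerVisit)) {
                splits <- lapply(tasks[ids], sampleSplit, config = config)
                batch <- .makeBatch(lapply(splits, `[[`, "contexts"),
                                    lapply(splits, `[[`, "targets"))
                model@layers <- layers
                res <- .npBatchLossGrad(model, batch)
                if (!is.finite(res$loss))
                    stop("meta-training diverged: non-finite objective at epoch ",
                         ep, " (batch of ", length(ids), " tasks)")
                g <- if (rep == 1L) res$grads else .addGrads(g, res$grads)
                bloss <- bloss + res$loss
            }
            if (splitsPerVisit > 1L)
                g <- lapply(g, .scaleGrads, s = 1 / splitsPerVisit)
            t <- t + 1L
            up <- .adamStep(layers, g, state, t, lr, clip)
            layers <- up$layers; state <- up$state
            epLoss <- epLoss + bloss / splitsPerVisit
            nBatches <- nBatches + 1L
        }
        objective[ep] <- epLoss / nBatches
    }
    model@layers <- layers
    report <- data.frame(epoch = seq_len(epochs), objective = objective)
    attr(report, "seed") <- seed
    attr(report, "config") <- config
    list(model = model, report = report)
}

#' Write a training report as TSV
#' @param report the report returned by \code{\link{metaTrain}}.
#' @param path output path.
#' @export
writeTrainReport <- function(report, path) {
    utils::write.table(report, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Predict in chunks of targets
#'
#' Splits the target set into chunks of at most \code{maxChunk} points and
#' decodes each chunk in a separate pass (bounding memory for very large
#' target sets). Because the decoder factorizes over targets, the result
#' equals \code{\link{npPredict}} on the full set regardless of the chunk
#' size.
#'
#' @param model an \linkS4class{NPModel}.
#' @param contexts labelled \code{\link{contextSet}}.
#' @param targetX target inputs (matrix or vector).
#' @param maxChunk maximum targets per pass (>= 1).
#' @return a \linkS4class{PredictiveGaussian}.
#' @export
chunkedPredict <- function(model, contexts, targetX, maxChunk = 1024L) {
    if (maxChunk < 1L) stop("maxChunk must be at least 1")
    if (!is.matrix(targetX)) targetX <- matrix(as.numeric(targetX), ncol = 1)
    Tn <- nrow(targetX)
    starts <- seq(1L, Tn, by = maxChunk)
    preds <- lapply(starts, function(s) {
        idx <- s:min(s + maxChunk - 1L, Tn)
        npPredict(model, contexts, targetX[idx, , drop = FALSE])
    })
    predictiveGaussian(unlist(lapply(preds, predMean)),
                       unlist(lapply(preds, predVar)))
}

#' Read a sampling/optimizer configuration from YAML or JSON
#'
#' The file may contain any of the \code{\link{samplingConfig}} fields plus
#' optimizer settings (\code{epochs}, \code{batchSize}, \code{lr},
#' \code{clip}, \code{seed}); unknown fields are preserved in the result.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return list with elements \code{sampling} (a samplingConfig) and
#'   \code{optimizer}.
#' @export
readTrainConfig <- function(path) {
    raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::fromJSON(path)
    sc <- samplingConfig(
        cRange = if (!is.null(raw$cRange)) raw$cRange else c(20L, 150L),
        tRange = if (!is.null(raw$tRange)) raw$tRange else c(20L, 150L),
        disjoint = isTRUE(raw$disjoint) || is.null(raw$disjoint),
        fraction = raw$fraction,
        allowOverlap = isTRUE(raw$allowOverlap))
    opt <- raw[intersect(names(raw), c("epochs", "batchSize", "lr", "clip",
                                       "seed", "splitsPerVisit"))]
    list(sampling = sc, optimizer = opt)
}
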