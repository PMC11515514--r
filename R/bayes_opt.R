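# Batched Bayesian optimization over a fixed molecular library with
# LCB / greedy / random acquisition, meta-training task augmentation from a
# complete score matrix, and an exact Tanimoto-kernel GP baseline.
# Sign convention: objectives are minimized (docking-score style); negate
# maximization objectives at ingestion.

#' Candidate library for Bayesian optimization
#'
#' Fixed pool of unique candidate molecules with precomputed input
#' representations and hidden objective values. The objective is accessed
#' only through evaluation during the BO loop.
#'
#' @param smiles character vector of unique molecules (or arbitrary ids).
#' @param X numeric matrix of input representations, one row per candidate.
#' @param objective hidden objective values (minimized), one per candidate.
#' @return a list of class \code{"candidateLibrary"}.
#' @export
candidateLibrary <- function(smiles, X, objective) {
    if (anyDuplicated(smiles)) stop("library molecules must be unique")
    if (nrow(X) != length(smiles) || length(objective) != length(smiles))
        stop("smiles, X and objective must be aligned")
    structure(list(smiles = smiles, X = X, objective = as.numeric(objective),
                   n = length(smiles)),
              class = "candidateLibrary")
}

#' Lower-confidence-bound acquisition scores
#'
#' \code{mu - kappa * sigma} under minimization: lower scores are more
#' attractive. \code{kappa = 0} reduces to greedy acquisition on the
#' predicted mean.
#'
#' @param pred a \linkS4class{PredictiveGaussian} over the candidates.
#' @param kappa non-negative exploration weight (default 1).
#' @return numeric score vector.
#' @export
lcb <- function(pred, kappa = 1) {
    if (kappa < 0) stop("kappa must be non-negative")
    predMean(pred) - kappa * sqrt(predVar(pred))
}

#' Select the next batch of unseen candidates
#'
#' The \code{batchSize} unseen candidates with the lowest acquisition
#' scores; ties are broken by lowest index.
#'
#' @param scores acquisition scores over the whole library.
#' @param seen logical mask of already-evaluated candidates.
#' @param batchSize number of candidates to select.
#' @return integer indices into the library.
#' @export
selectBatch <- function(scores, seen, batchSize) {
    unseen <- which(!seen)
    if (length(unseen) < batchSize)
        stop("only ", length(unseen), " unseen candidates, need ", batchSize)
    unseen[order(scores[unseen], unseen)[seq_len(batchSize)]]
}

#' Run batched Bayesian optimization over a candidate library
#'
#' Initializes with \code{nInit} random evaluations, then repeats: condition
#' the surrogate on all seen (molecule, value) pairs as contexts, score all
#' unseen candidates with the acquisition function, evaluate the best
#' batch, and record the monotone best-so-far curve, stopping when the
#' evaluation budget is spent.
#'
#' @param surrogate function(contexts, targetX) returning a
#'   \linkS4class{PredictiveGaussian} over the rows of targetX — e.g. a
#'   wrapper around \code{\link{chunkedPredict}} for a neural process
#'   (optionally fine-tuning first) or \code{\link{tanimotoGpFitPredict}}.
#'   Ignored for random acquisition.
#' @param library a \code{\link{candidateLibrary}}.
#' @param acquisition "lcb", "greedy" or "random".
#' @param batchSize molecules evaluated per iteration (default 5).
#' @param budget total evaluation budget (default 1000).
#' @param kappa LCB exploration weight (default 1).
#' @param nInit initial random evaluations (default 20).
#' @param seed RNG seed (initial batch; random acquisition).
#' @return a \linkS4class{BOTrajectory}.
#' @export
runBO <- function(surrogate, library, acquisition = c("lcb", "greedy", "random"),
                  batchSize = 5L, budget = 1000L, kappa = 1, nInit = 20L,
                  seed = 1L) {
    acquisition <- match.arg(acquisition)
    stopifnot(inherits(library, "candidateLibrary"))
    if (budget < nInit) stop("budget must cover the initial evaluations")
    if (library$n <= budget) stop("library must be larger than the budget")
    set.seed(seed)
    seen <- logical(library$n)
    evalIdx <- sample.int(library$n, nInit)
    seen[evalIdx] <- TRUE
    iteration <- rep(0L, nInit)
    it <- 0L
    while (sum(seen) + batchSize <= budget) {
        it <- it + 1L
        unseenX <- library$X[!seen, , drop = FALSE]
        if (acquisition == "random") {
            picks <- sample(which(!seen), batchSize)
        } else {
            ctx <- contextSet(library$X[seen, , drop = FALSE],
                              library$objective[seen])
            pred <- surrogate(ctx, library$X)
            scores <- if (acquisition == "lcb") lcb(pred, kappa)
                      else predMean(pred)
            picks <- selectBatch(scores, seen, batchSize)
        }
        seen[picks] <- TRUE
        evalIdx <- c(evalIdx, picks)
        iteration <- c(iteration, rep(it, batchSize))
    }
    values <- library$objective[evalIdx]
    new("BOTrajectory", iteration = as.integer(iteration),
        index = as.integer(evalIdx), value = values,
        bestSoFar = cummin(values),
        config = list(acquisition = acquisition, batchSize = batchSize,
                      budget = budget, kappa = kappa, nInit = nInit,
                      seed = seed))
}

#' Write a BO trajectory as TSV
#' @param trajectory a \linkS4class{BOTrajectory}.
#' @param library the \code{\link{candidateLibrary}} it ran on (for SMILES).
#' @param path output path.
#' @export
writeTrajectory <- function(trajectory, library, path) {
    df <- data.frame(iteration = trajectory@iteration,
                     smiles = library$smiles[trajectory@index],
                     objective = trajectory@value,
                     bestSoFar = trajectory@bestSoFar)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Augment meta-training tasks from a score matrix
#'
#' Draws \code{n} random transforms of a complete molecules-x-targets score
#' matrix — a scalar multiple of one target, a random-weight linear
#' combination of two targets, or the elementwise minimum / maximum of one
#' target with its median — each additively combined with a weighted QED
#' column. Transforms touching an excluded target (e.g. proteins that enter
#' a BO objective) are discarded, so the returned count can be below
#' \code{n}.
#'
#' @param scores complete numeric matrix (molecules x targets) with column
#'   names.
#' @param qed drug-likeness scores aligned with the rows.
#' @param n transforms to draw.
#' @param exclude character vector of target names to exclude.
#' @param seed RNG seed.
#' @return list of augmented tasks; each has \code{labels}, \code{sources}
#'   (target names used) and a human-readable \code{description}.
#' @export
augmentTasks <- function(scores, qed, n, exclude = character(0), seed = 1L) {
    if (any(is.na(scores))) stop("score matrix must be complete")
    if (length(qed) != nrow(scores)) stop("qed must align with molecules")
    targets <- colnames(scores)
    if (all(targets %in% exclude)) stop("exclusion set covers all targets")
    set.seed(seed)
    out <- vector("list", n)
    kept <- 0L
    for (i in seq_len(n)) {
        kind <- sample(c("scalar", "linear", "min", "max"), 1L)
        nsrc <- if (kind == "linear") 2L else 1L
        src <- sample(targets, nsrc)
        if (any(src %in% exclude)) next
        wq <- stats::runif(1, 0.5, 2)
        if (kind == "scalar") {
            w <- stats::runif(1, 0.1, 1)
            labels <- w * scores[, src]
            desc <- sprintf("%.3f*%s", w, src)
        } else if (kind == "linear") {
            w <- stats::runif(2, 0.1, 1)
            labels <- as.numeric(scores[, src] %*% w)
            desc <- sprintf("%.3f*%s + %.3f*%s", w[1], src[1], w[2], src[2])
        } else {
            med <- stats::median(scores[, src])
            labels <- if (kind == "min") pmin(scores[, src], med)
                      else pmax(scores[, src], med)
            desc <- sprintf("%s(%s, median=%.3f)", kind, src, med)
        }
        labels <- labels + wq * qed
        kept <- kept + 1L
        out[[kept]] <- list(labels = as.numeric(labels), sources = src,
                            description = sprintf("%s + %.3f*QED", desc, wq))
    }
    out[seq_len(kept)]
}

#' Exact Tanimoto-kernel Gaussian-process regression
#'
#' GP posterior with kernel k(a, b) = Tanimoto(a, b) on binary
#' fingerprints and observation noise on the diagonal, computed exactly by
#' Cholesky factorization (with a 1e-8 jitter retry if the factorization
#' fails).
#'
#' @param trainFps training fingerprints (\linkS4class{Fingerprints} or
#'   binary matrix, >= 1 row).
#' @param trainY training labels.
#' @param testFps test fingerprints.
#' @param noise observation noise variance (> 0).
#' @return a \linkS4class{PredictiveGaussian} over the test molecules
#'   (latent-function posterior; variances do not include the observation
#'   noise).
#' @export
tanimotoGpFitPredict <- function(trainFps, trainY, testFps, noise = 0.1) {
    if (noise <= 0) stop("noise must be positive")
    Xtr <- .bitsOf(trainFps, "training fingerprints")
    if (nrow(Xtr) < 1L) stop("need at least 1 training point")
    if (length(trainY) != nrow(Xtr)) stop("trainY must align with trainFps")
    Xte <- .bitsOf(testFps, "test fingerprints")
    K <- .tanimotoCross(Xtr, Xtr)
    Ks <- .tanimotoCross(Xte, Xtr)
    A <- K + diag(noise, nrow(K))
    L <- tryCatch(chol(A), error = function(e)
        tryCatch(chol(A + diag(1e-8, nrow(A))), error = function(e2)
            stop("Tanimoto kernel matrix is not positive definite")))
    alpha <- backsolve(L, forwardsolve(t(L), trainY))
    mu <- as.numeric(Ks %*% alpha)
    Vhalf <- forwardsolve(t(L), t(Ks))
    var <- pmax(1 - colSums(Vhalf^2), 1e-12)   # prior k(x,x) = 1
    predictiveGaussian(mu, var)
}
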