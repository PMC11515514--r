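# Conditional and latent neural processes: encoding, mean aggregation,
# Gaussian decoding, training objectives and their analytic gradients.
#
# Model: each labelled context (x_j, y_j) is mapped by the encoder h_theta
# to a per-point encoding r_j; the global function encoding r is the mean of
# the r_j (commutative => invariant to context permutations; empty context
# set encodes to the zero vector). The decoder g_theta maps (r, x) to a
# predictive mean and raw scale, with variance softplus(raw) + floor. The
# LNP adds a latent path: r is mapped to a diagonal Gaussian over z, and z
# (a reparameterized sample at training time, the posterior mean at test
# time) is decoded instead of r. Targets are conditionally independent given
# the encoding, so the predictive factorizes over target points.

#' Construct a neural process model
#'
#' @param kind "CNP" (deterministic encoding) or "LNP" (latent-variable
#'   encoding).
#' @param dimX input dimension (fingerprint length, graph-encoder output
#'   length, or 1 for scalar inputs).
#' @param hidden hidden width of encoder/decoder layers (default 128).
#' @param rDim length of the global function encoding r (default 128).
#' @param zDim length of the latent variable z, LNP only (default 64).
#' @param latentHidden hidden width of the latent path (default 64).
#' @param varianceFloor additive floor on predictive variances (default 1e-4),
#'   preventing degenerate likelihood spikes.
#' @param seed RNG seed for weight initialization.
#' @param featurizer optional featurizer configuration list stored with the
#'   model so representation mismatches are detectable.
#' @return an \linkS4class{NPModel}.
#' @export
npModel <- function(kind = c("CNP", "LNP"), dimX, hidden = 128L, rDim = 128L,
                    zDim = 64L, latentHidden = 64L, varianceFloor = 1e-4,
                    seed = 1L, featurizer = NULL) {
    kind <- match.arg(kind)
    set.seed(seed)
    decIn <- if (kind == "LNP") zDim + dimX else rDim + dimX
    layers <- list(
        encoder = .heInit(c(dimX + 1L, hidden, hidden, rDim)),
        decoder = .heInit(c(decIn, hidden, hidden, 2L)))
    if (kind == "LNP")
        layers$latent <- .heInit(c(rDim, latentHidden, 2L * zDim))
    new("NPModel", kind = kind, layers = layers,
        config = list(dimX = as.integer(dimX), hidden = as.integer(hidden),
                      rDim = as.integer(rDim), zDim = as.integer(zDim),
                      latentHidden = as.integer(latentHidden),
                      varianceFloor = varianceFloor, aggregation = "mean",
                      featurizer = featurizer))
}

.checkInputDim <- function(model, X, what) {
    if (ncol(X) != model@config$dimX)
        stop(what, " dimension (", ncol(X),
             ") does not match the model input dimension (", model@config$dimX, ")")
}

# mean-aggregate per-point encodings R by task id into an nTasks x rDim
# matrix; tasks with no points aggregate to the zero vector
.aggregateByTask <- function(R, taskIds, nTasks) {
    agg <- matrix(0, nTasks, ncol(R))
    if (nrow(R)) {
        rs <- rowsum(R, group = taskIds)
        ids <- as.integer(rownames(rs))
        cnt <- tabulate(taskIds, nbins = nTasks)
        agg[ids, ] <- rs / cnt[ids]
    }
    agg
}

#' Encode a context set into a global function encoding
#'
#' Applies the encoder h_theta to every labelled context pair and combines
#' the per-point encodings by the mean (a commutative aggregation, so the
#' result is invariant to context permutations). An empty context set
#' encodes to the zero vector.
#'
#' @param model an \linkS4class{NPModel}.
#' @param contexts a \code{\link{contextSet}} with labels (y required).
#' @param keepPointEncodings keep the per-context encodings r_j?
#' @return list with \code{r} (numeric vector, the global encoding) and,
#'   if requested, \code{rJ} (matrix of per-context encodings).
#' @export
encodeContexts <- function(model, contexts, keepPointEncodings = FALSE) {
    stopifnot(is(model, "NPModel"))
    if (contexts$size == 0L) {
        r <- numeric(model@config$rDim)
        return(list(r = r, rJ = if (keepPointEncodings)
            matrix(numeric(0), 0, model@config$rDim) else NULL))
    }
    if (is.null(contexts$y)) stop("contexts must carry labels")
    .checkInputDim(model, contexts$x, "context")
    R <- .mlpForward(model@layers$encoder, cbind(contexts$x, contexts$y))$out
    list(r = colMeans(R), rJ = if (keepPointEncodings) R else NULL)
}

.decodeGaussian <- function(model, decIn) {
    out <- .mlpForward(model@layers$decoder, decIn)$out
    if (any(!is.finite(out)))
        stop("numerical failure in decoder: non-finite activations ",
             "(inputs in [", min(decIn), ", ", max(decIn), "])")
    predictiveGaussian(out[, 1], .softplus(out[, 2]) + model@config$varianceFloor)
}

#' Variational posterior over the latent variable (LNP)
#'
#' Encodes a labelled data set and maps the aggregated encoding through the
#' latent path to a diagonal Gaussian over z.
#'
#' @param model an LNP \linkS4class{NPModel}.
#' @param data a labelled \code{\link{contextSet}} (nonempty).
#' @return list with \code{mean} and \code{variance} vectors of length zDim.
#' @export
lnpPosterior <- function(model, data) {
    stopifnot(is(model, "NPModel"))
    if (model@kind != "LNP") stop("lnpPosterior requires an LNP model")
    if (data$size == 0L) stop("data must be nonempty")
    r <- encodeContexts(model, data)$r
    out <- .mlpForward(model@layers$latent, matrix(r, 1))$out
    z <- model@config$zDim
    list(mean = out[1, seq_len(z)],
         variance = .softplus(out[1, z + seq_len(z)]) + 1e-6)
}

#' Predict a Gaussian distribution at target inputs
#'
#' Conditions the model on a (possibly empty) context set and decodes each
#' target input to a predictive mean and variance. CNP prediction is
#' deterministic. For the LNP the decoder consumes the posterior mean of z
#' by default; \code{nSamples > 1} instead averages a Gaussian mixture over
#' reparameterized posterior samples (moment-matched mean and variance).
#'
#' @param model an \linkS4class{NPModel}.
#' @param contexts labelled \code{\link{contextSet}}.
#' @param targetX numeric matrix of target inputs (rows = targets), or a
#'   vector for 1D inputs.
#' @param nSamples number of latent samples (LNP only; default 1 = use the
#'   posterior mean, deterministic).
#' @param seed RNG seed used when \code{nSamples > 1}.
#' @return a \linkS4class{PredictiveGaussian} aligned with the rows of
#'   \code{targetX}.
#' @export
npPredict <- function(model, contexts, targetX, nSamples = 1L, seed = 1L) {
    stopifnot(is(model, "NPModel"))
    if (!is.matrix(targetX)) targetX <- matrix(as.numeric(targetX), ncol = 1)
    if (nrow(targetX) == 0L) stop("targetX must be nonempty")
    .checkInputDim(model, targetX, "target")
    Tn <- nrow(targetX)
    if (model@kind == "CNP") {
        r <- encodeContexts(model, contexts)$r
        decIn <- cbind(matrix(r, Tn, length(r), byrow = TRUE), targetX)
        return(.decodeGaussian(model, decIn))
    }
    post <- lnpPosterior(model, contexts)
    if (nSamples <= 1L) {
        decIn <- cbind(matrix(post$mean, Tn, length(post$mean), byrow = TRUE),
                       targetX)
        return(.decodeGaussian(model, decIn))
    }
    set.seed(seed)
    mus <- matrix(0, Tn, nSamples); vars <- matrix(0, Tn, nSamples)
    for (s in seq_len(nSamples)) {
        z <- post$mean + sqrt(post$variance) * stats::rnorm(length(post$mean))
        p <- .decodeGaussian(model, cbind(matrix(z, Tn, length(z), byrow = TRUE),
                                          targetX))
        mus[, s] <- predMean(p); vars[, s] <- predVar(p)
    }
    m <- rowMeans(mus)
    predictiveGaussian(m, rowMeans(vars + mus^2) - m^2 + 1e-12)
}

#' Log predictive density of labels under a Gaussian prediction
#'
#' Sum over targets of log N(y_j; mu_j, sigma2_j) — the factorized
#' predictive log-likelihood.
#'
#' @param pred a \linkS4class{PredictiveGaussian}.
#' @param y observed labels, same length as the prediction.
#' @return scalar log density.
#' @export
logPredictiveDensity <- function(pred, y) {
    stopifnot(is(pred, "PredictiveGaussian"))
    if (length(y) != length(pred@mean)) stop("prediction and label lengths differ")
    sum(stats::dnorm(y, pred@mean, sqrt(pred@variance), log = TRUE))
}

#' KL divergence between diagonal Gaussians
#'
#' KL(N(mean1, var1) || N(mean0, var0)), summed over dimensions.
#'
#' @param mean1,var1 moments of the first (posterior) Gaussian.
#' @param mean0,var0 moments of the second (prior) Gaussian.
#' @return scalar KL divergence.
#' @export
klDiagGaussian <- function(mean1, var1, mean0, var0) {
    sum(0.5 * (log(var0 / var1) + (var1 + (mean1 - mean0)^2) / var0 - 1))
}

#' CNP training loss on one context/target split
#'
#' Negative predictive log-likelihood of the targets given the contexts,
#' i.e. \code{-logPredictiveDensity(npPredict(model, contexts, x_t), y_t)}.
#' The meta-training loop averages this per-task loss over tasks.
#'
#' @param model a CNP \linkS4class{NPModel}.
#' @param contexts labelled \code{\link{contextSet}}.
#' @param targets labelled \code{\link{contextSet}} of targets.
#' @return scalar loss.
#' @export
cnpLoss <- function(model, contexts, targets) {
    if (is.null(targets$y)) stop("targets must carry labels")
    -logPredictiveDensity(npPredict(model, contexts, targets$x), targets$y)
}

#' LNP training loss on one context/target split
#'
#' Single-sample variational objective: negative reparameterized predictive
#' log-likelihood of the targets with z drawn from the posterior conditioned
#' on contexts-and-targets, plus KL(posterior(contexts+targets) ||
#' posterior(contexts)). The KL regularizer reduces the sensitivity of the
#' encoding to any one sample of the task's observations.
#'
#' @param model an LNP \linkS4class{NPModel}.
#' @param contexts labelled \code{\link{contextSet}}.
#' @param targets labelled \code{\link{contextSet}}.
#' @param seed RNG seed for the reparameterized sample.
#' @return scalar loss.
#' @export
lnpLoss <- function(model, contexts, targets, seed = 1L) {
    if (model@kind != "LNP") stop("lnpLoss requires an LNP model")
    if (is.null(targets$y)) stop("targets must carry labels")
    set.seed(seed)
    eps <- matrix(stats::rnorm(model@config$zDim), 1)
    batch <- .makeBatch(list(contexts), list(targets))
    .lnpBatch(model, batch, eps, wantGrads = FALSE)$loss
}

# --- batched forward/backward ---------------------------------------------

# batch representation: ragged rows + task index vectors (equivalent to a
# padded 3D task batch, without masking)
.makeBatch <- function(contextList, targetList) {
    B <- length(contextList)
    Xc <- do.call(rbind, lapply(contextList, `[[`, "x"))
    yc <- unlist(lapply(contextList, `[[`, "y"), use.names = FALSE)
    taskc <- rep(seq_len(B), vapply(contextList, `[[`, 0L, "size"))
    Xt <- do.call(rbind, lapply(targetList, `[[`, "x"))
    yt <- unlist(lapply(targetList, `[[`, "y"), use.names = FALSE)
    taskt <- rep(seq_len(B), vapply(targetList, `[[`, 0L, "size"))
    list(Xc = Xc, yc = yc, taskc = taskc, Xt = Xt, yt = yt, taskt = taskt, B = B)
}

.gaussNllParts <- function(mu, sraw, y, floor, w) {
    sig2 <- .softplus(sraw) + floor
    nll <- 0.5 * log(2 * pi * sig2) + (y - mu)^2 / (2 * sig2)
    dmu <- w * (mu - y) / sig2
    dsig2 <- w * 0.5 * (1 / sig2 - (y - mu)^2 / sig2^2)
    list(loss = w * sum(nll), dOut = cbind(dmu, dsig2 * .sigmoid(sraw)))
}

.cnpBatch <- function(model, batch, wantGrads = TRUE) {
    ly <- model@layers; B <- batch$B
    rDim <- model@config$rDim
    fe <- .mlpForward(ly$encoder, cbind(batch$Xc, batch$yc))
    agg <- .aggregateByTask(fe$out, batch$taskc, B)
    decIn <- cbind(agg[batch$taskt, , drop = FALSE], batch$Xt)
    fd <- .mlpForward(ly$decoder, decIn)
    parts <- .gaussNllParts(fd$out[, 1], fd$out[, 2], batch$yt,
                            model@config$varianceFloor, 1 / B)
    if (!wantGrads) return(list(loss = parts$loss))
    bd <- .mlpBackward(ly$decoder, fd, parts$dOut)
    dAgg <- .aggregateSumByTask(bd$dX[, seq_len(rDim), drop = FALSE],
                                batch$taskt, B)
    cnt <- tabulate(batch$taskc, nbins = B)
    dR <- dAgg[batch$taskc, , drop = FALSE] / cnt[batch$taskc]
    be <- .mlpBackward(ly$encoder, fe, dR)
    list(loss = parts$loss,
         grads = list(encoder = be$grads, decoder = bd$grads))
}

.aggregateSumByTask <- function(R, taskIds, nTasks) {
    agg <- matrix(0, nTasks, ncol(R))
    if (nrow(R)) {
        rs <- rowsum(R, group = taskIds)
        agg[as.integer(rownames(rs)), ] <- rs
    }
    agg
}

.lnpBatch <- function(model, batch, eps, wantGrads = TRUE) {
    ly <- model@layers; B <- batch$B
    zDim <- model@config$zDim; zFloor <- 1e-6
    Xf <- rbind(batch$Xc, batch$Xt); yf <- c(batch$yc, batch$yt)
    taskf <- c(batch$taskc, batch$taskt)
    feF <- .mlpForward(ly$encoder, cbind(Xf, yf))
    aggF <- .aggregateByTask(feF$out, taskf, B)
    feC <- .mlpForward(ly$encoder, cbind(batch$Xc, batch$yc))
    aggC <- .aggregateByTask(feC$out, batch$taskc, B)
    lfF <- .mlpForward(ly$latent, aggF)
    lfC <- .mlpForward(ly$latent, aggC)
    iM <- seq_len(zDim); iS <- zDim + iM
    mF <- lfF$out[, iM, drop = FALSE]; s2F <- .softplus(lfF$out[, iS, drop = FALSE]) + zFloor
    mC <- lfC$out[, iM, drop = FALSE]; s2C <- .softplus(lfC$out[, iS, drop = FALSE]) + zFloor
    z <- mF + sqrt(s2F) * eps
    decIn <- cbind(z[batch$taskt, , drop = FALSE], batch$Xt)
    fd <- .mlpForward(ly$decoder, decIn)
    w <- 1 / B
    parts <- .gaussNllParts(fd$out[, 1], fd$out[, 2], batch$yt,
                            model@config$varianceFloor, w)
    kl <- 0.5 * (log(s2C / s2F) + (s2F + (mF - mC)^2) / s2C - 1)
    loss <- parts$loss + w * sum(kl)
    if (!wantGrads) return(list(loss = loss))

    bd <- .mlpBackward(ly$decoder, fd, parts$dOut)
    dzTask <- .aggregateSumByTask(bd$dX[, seq_len(zDim), drop = FALSE],
                                  batch$taskt, B)
    dmF <- dzTask + w * (mF - mC) / s2C
    ds2F <- dzTask * eps * 0.5 / sqrt(s2F) + w * 0.5 * (1 / s2C - 1 / s2F)
    dmC <- -w * (mF - mC) / s2C
    ds2C <- w * 0.5 * (1 / s2C - (s2F + (mF - mC)^2) / s2C^2)
    dLatF <- cbind(dmF, ds2F * .sigmoid(lfF$out[, iS, drop = FALSE]))
    dLatC <- cbind(dmC, ds2C * .sigmoid(lfC$out[, iS, drop = FALSE]))
    blF <- .mlpBackward(ly$latent, lfF, dLatF)
    blC <- .mlpBackward(ly$latent, lfC, dLatC)
    cntF <- tabulate(taskf, nbins = B); cntC <- tabulate(batch$taskc, nbins = B)
    dRF <- blF$dX[taskf, , drop = FALSE] / cntF[taskf]
    dRC <- blC$dX[batch$taskc, , drop = FALSE] / cntC[batch$taskc]
    beF <- .mlpBackward(ly$encoder, feF, dRF)
    beC <- .mlpBackward(ly$encoder, feC, dRC)
    list(loss = loss,
         grads = list(encoder = .addGrads(beF$grads, beC$grads),
                      decoder = bd$grads,
                      latent = .addGrads(blF$grads, blC$grads)))
}

.npBatchLossGrad <- function(model, batch, wantGrads = TRUE, eps = NULL) {
    if (model@kind == "CNP") return(.cnpBatch(model, batch, wantGrads))
    if (is.null(eps))
        eps <- matrix(stats::rnorm(batch$B * model@config$zDim), batch$B)
    .lnpBatch(model, batch, eps, wantGrads)
}

# --- checkpointing ---------------------------------------------------------

#' Save / load a neural process checkpoint
#'
#' A checkpoint is a single archive holding the weights, the featurizer
#' configuration and all architecture settings (aggregation, variance
#' floor). The weight round trip is bit-stable.
#'
#' @param model an \linkS4class{NPModel}.
#' @param path file path for the checkpoint archive.
#' @return \code{loadNPModel} returns the restored \linkS4class{NPModel};
#'   \code{saveNPModel} returns \code{path} invisibly.
#' @export
saveNPModel <- function(model, path) {
    stopifnot(is(model, "NPModel"))
    saveRDS(list(kind = model@kind, layers = model@layers,
                 config = model@config, format = 1L), path)
    invisible(path)
}

#' @rdname saveNPModel
#' @export
loadNPModel <- function(path) {
    obj <- readRDS(path)
    new("NPModel", kind = obj$kind, layers = obj$layers, config = obj$config)
}
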