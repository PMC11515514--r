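# Fine-tuning: adapting NP parameters to a meta-test function by mimicking
# the meta-training procedure on the function's own contexts, with layer
# freezing to limit overfitting.

#' Fine-tuning configuration
#'
#' Controls the adaptation of a trained neural process to one meta-test
#' function: the test function's C contexts are repeatedly re-split into
#' new contexts (C') and new targets (T'), and the NP objective is
#' backpropagated through a small adaptable subset of layers (by default
#' the last two decoder layers, plus the last two latent-path layers for an
#' LNP) while everything else stays frozen.
#'
#' @param eETarget desired effective epochs (default 20).
#' @param cNew new-context size C' per adaptation epoch (default 20; use 5
#'   for 20-shot tasks, see \code{fineTunePreset20Shot}).
#' @param tNew new-target size T' per adaptation epoch (default 20).
#' @param adaptable layer selector: "last2" (default) or a character vector
#'   of "group.index" layer ids (e.g. \code{c("decoder.2", "decoder.3")}).
#' @param lr learning rate (default 1e-4, an order below meta-training).
#' @param effectiveEpochMode "target" counts target views only when
#'   converting effective epochs to actual epochs (e = ceil(eE * C / T'));
#'   "both" counts context and target views (e = ceil(eE * C / (C' + T'))).
#' @return a list of class \code{"fineTuneConfig"}.
#' @export
fineTuneConfig <- function(eETarget = 20, cNew = 20L, tNew = 20L,
                           adaptable = "last2", lr = 1e-4,
                           effectiveEpochMode = c("target", "both")) {
    if (eETarget < 0) stop("eETarget must be non-negative")
    if (cNew < 1L || tNew < 1L) stop("cNew and tNew must be at least 1")
    structure(list(eETarget = eETarget, cNew = as.integer(cNew),
                   tNew = as.integer(tNew), adaptable = adaptable, lr = lr,
                   effectiveEpochMode = match.arg(effectiveEpochMode)),
              class = "fineTuneConfig")
}

#' 20-shot fine-tuning preset (C' = T' = 5)
#' @param ... overrides passed to \code{\link{fineTuneConfig}}.
#' @export
fineTunePreset20Shot <- function(...) fineTuneConfig(cNew = 5L, tNew = 5L, ...)

#' Actual epochs needed for a desired number of effective epochs
#'
#' Inverts the effective-epoch relation for fine-tuning: with C original
#' contexts re-split into T' targets per epoch, each point is seen as a
#' target about T'/C times per epoch, so e = ceil(eE * C / T') epochs give
#' eE effective epochs of target views. With \code{mode = "both"}, context
#' views count too and e = ceil(eE * C / (C' + T')).
#'
#' @param eE desired effective epochs.
#' @param C number of available contexts of the test function.
#' @param tNew new-target size T' per epoch.
#' @param cNew new-context size C' (used by mode "both").
#' @param mode "target" (default) or "both".
#' @return integer number of epochs.
#' @export
epochsForEffective <- function(eE, C, tNew, cNew = tNew,
                               mode = c("target", "both")) {
    mode <- match.arg(mode)
    if (C < 1L) stop("C must be at least 1")
    if (tNew < 1L) stop("tNew must be at least 1")
    denom <- if (mode == "target") tNew else cNew + tNew
    as.integer(ceiling(eE * C / denom))
}

.layerIds <- function(model) {
    unlist(lapply(names(model@layers), function(g)
        sprintf("%s.%d", g, seq_along(model@layers[[g]]))))
}

#' Select the adaptable parameter subset
#'
#' With the default "last2" selector: the final two decoder layers
#' (the last layer being the mu/sigma2 head) for a CNP, additionally the
#' final two latent-path layers for an LNP; all other layers are frozen.
#' Custom selectors name layers as "group.index".
#'
#' @param model an \linkS4class{NPModel}.
#' @param config a \code{\link{fineTuneConfig}}.
#' @return character vector of adaptable layer ids; the complement of the
#'   frozen set (the two partition all parameters).
#' @export
selectAdaptable <- function(model, config = fineTuneConfig()) {
    stopifnot(is(model, "NPModel"))
    sel <- config$adaptable
    all <- .layerIds(model)
    if (identical(sel, "last2")) {
        nd <- length(model@layers$decoder)
        ids <- sprintf("decoder.%d", c(nd - 1L, nd))
        if (model@kind == "LNP") {
            nl <- length(model@layers$latent)
            ids <- c(ids, sprintf("latent.%d", c(nl - 1L, nl)))
        }
        return(ids)
    }
    bad <- setdiff(sel, all)
    if (length(bad))
        stop("unknown layer id(s): ", paste(bad, collapse = ", "))
    sel
}

.maskFromIds <- function(model, ids) {
    lapply(stats::setNames(names(model@layers), names(model@layers)),
           function(g) sprintf("%s.%d", g, seq_along(model@layers[[g]])) %in% ids)
}

#' Fine-tune a neural process on a test function's contexts
#'
#' Mimics meta-training on a single function: for the number of epochs
#' implied by the desired effective epochs, the C labelled contexts are
#' split into fresh disjoint new-context (C') and new-target (T') subsets
#' and one Adam step on the NP objective is taken, updating only the
#' adaptable layers (see \code{\link{selectAdaptable}}); frozen layers are
#' returned bitwise unchanged.
#'
#' @param model a trained \linkS4class{NPModel}.
#' @param contexts labelled \code{\link{contextSet}} of the test function
#'   (C >= cNew + tNew).
#' @param config a \code{\link{fineTuneConfig}}.
#' @param seed RNG seed for the split draws (and latent samples for LNPs).
#' @return the adapted \linkS4class{NPModel}.
#' @export
fineTune <- function(model, contexts, config = fineTuneConfig(), seed = 1L) {
    stopifnot(is(model, "NPModel"))
    if (is.null(contexts$y)) stop("contexts must carry labels")
    C <- contexts$size
    if (C < config$cNew + config$tNew)
        stop("need C >= cNew + tNew contexts to fine-tune (have ", C,
             ", need ", config$cNew + config$tNew,
             "); lower cNew/tNew, e.g. fineTunePreset20Shot()")
    e <- epochsForEffective(config$eETarget, C, config$tNew, config$cNew,
                            config$effectiveEpochMode)
    if (e == 0L) return(model)
    ids <- selectAdaptable(model, config)
    mask <- .maskFromIds(model, ids)
    set.seed(seed)
    layers <- model@layers
    state <- .adamInit(layers)
    task <- taskObservations(contexts$x, contexts$y)
    split <- samplingConfig(cRange = c(config$cNew, config$cNew + 1L),
                            tRange = c(config$tNew, config$tNew + 1L))
    for (t in seq_len(e)) {
        sp <- sampleSplit(task, split)
        batch <- .makeBatch(list(sp$contexts), list(sp$targets))
        model@layers <- layers
        res <- .npBatchLossGrad(model, batch)
        if (!is.finite(res$loss))
            stop("fine-tuning diverged: non-finite objective at epoch ", t)
        up <- .adamStep(layers, res$grads, state, t, config$lr, mask = mask)
        layers <- up$layers; state <- up$state
    }
    model@layers <- layers
    model
}
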