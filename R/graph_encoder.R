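# Molecular-graph encoder: atom/bond pre-embedding, QKV-attention message
# passing over direct neighbours, then a superatom stage where a virtual
# node connected to every atom accumulates the whole-molecule state, which
# a small FNN maps to the final length-50 molecular representation.

#' Initialize graph-encoder parameters
#'
#' Pre-embedding: a 2-layer FNN (50 hidden units) maps atom features to
#' length-25 vectors and bond features to length-25 vectors (summed over
#' each atom's bonds), concatenated into a length-50 atom state. Message
#' passing: per round, single-head scaled-dot-product attention over each
#' atom's neighbour set with queries/keys from a single-layer FNN and
#' values from a linear map, followed by a residual add and a linear +
#' ReLU update. Separate weights per round and per stage (neighbour /
#' superatom); a final 2-layer FNN maps the superatom state to the
#' molecular representation.
#'
#' @param dAtom,dBond feature dimensions (defaults match
#'   \code{\link{smilesToGraph}}).
#' @param stateDim atom-state width (default 50).
#' @param embedDim per-block embedding width (default 25).
#' @param hidden pre-embedding hidden width (default 50).
#' @param rounds message-passing rounds per stage (default 3).
#' @param seed RNG seed.
#' @return a list of class \code{"graphEncoderParams"}.
#' @export
graphEncoderParams <- function(dAtom = 44L, dBond = 10L, stateDim = 50L,
                               embedDim = 25L, hidden = 50L, rounds = 3L,
                               seed = 1L) {
    if (rounds < 0L) stop("rounds must be non-negative")
    set.seed(seed)
    attnRound <- function() {
        sd <- sqrt(1 / stateDim)
        list(Wq = matrix(stats::rnorm(stateDim^2, sd = sd), stateDim),
             bq = numeric(stateDim),
             Wk = matrix(stats::rnorm(stateDim^2, sd = sd), stateDim),
             bk = numeric(stateDim),
             Wv = matrix(stats::rnorm(stateDim^2, sd = sd), stateDim),
             Wu = matrix(stats::rnorm(stateDim^2, sd = sd), stateDim),
             bu = numeric(stateDim))
    }
    structure(list(
        atomEmbed = .heInit(c(dAtom, hidden, embedDim)),
        bondEmbed = .heInit(c(dBond, hidden, embedDim)),
        neighbour = lapply(seq_len(rounds), function(i) attnRound()),
        super = lapply(seq_len(rounds), function(i) attnRound()),
        final = .heInit(c(stateDim, hidden, stateDim)),
        config = list(dAtom = dAtom, dBond = dBond, stateDim = stateDim,
                      embedDim = embedDim, hidden = hidden, rounds = rounds,
                      seed = seed)),
        class = "graphEncoderParams")
}

.checkGraphDims <- function(graph, params) {
    if (ncol(graph@atomFeatures) != params$config$dAtom)
        stop("atom feature dimension mismatch: graph has ",
             ncol(graph@atomFeatures), ", encoder expects ", params$config$dAtom)
    if (nrow(graph@bondFeatures) && ncol(graph@bondFeatures) != params$config$dBond)
        stop("bond feature dimension mismatch: graph has ",
             ncol(graph@bondFeatures), ", encoder expects ", params$config$dBond)
}

#' Pre-embed atoms and bonds into atom states
#'
#' Atom features pass through the atom FNN to length-25 vectors; each
#' directed bond's features pass through the bond FNN and are summed over
#' each atom's incident bonds (an atom with no bonds gets the zero vector,
#' the empty-sum convention). Concatenation gives the length-50 initial
#' atom state.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param params \code{\link{graphEncoderParams}}.
#' @return matrix nAtoms x stateDim with attribute \code{stage = "pre"}.
#' @export
embedAtomsAndBonds <- function(graph, params) {
    stopifnot(is(graph, "MolecularGraph"))
    .checkGraphDims(graph, params)
    n <- graph@nAtoms
    atomPart <- .mlpForward(params$atomEmbed, graph@atomFeatures)$out
    bondPart <- matrix(0, n, params$config$embedDim)
    if (nrow(graph@edges)) {
        be <- .mlpForward(params$bondEmbed, graph@bondFeatures)$out
        # bond row e describes edge (from, to): accumulate on the receiving atom
        bondPart <- .aggregateSumByTask(be, graph@edges[, 2], n)
    }
    states <- cbind(atomPart, bondPart)
    attr(states, "stage") <- "pre"
    states
}

# one attention round over a directed edge list; returns updated states.
# atoms that receive no edges pass through unchanged.
.attentionRound <- function(states, edges, w) {
    n <- nrow(states)
    from <- edges[, 1]; to <- edges[, 2]
    Q <- sweep(states %*% w$Wq, 2, w$bq, "+")
    K <- sweep(states %*% w$Wk, 2, w$bk, "+")
    V <- states %*% w$Wv
    logit <- rowSums(Q[to, , drop = FALSE] * K[from, , drop = FALSE]) /
        sqrt(ncol(states))
    mx <- tapply(logit, to, max)
    ex <- exp(logit - mx[as.character(to)])
    denom <- tapply(ex, to, sum)
    a <- as.numeric(ex / denom[as.character(to)])
    msg <- .aggregateSumByTask(V[from, , drop = FALSE] * a, to, n)
    upd <- pmax(sweep((states + msg) %*% w$Wu, 2, w$bu, "+"), 0)
    receives <- unique(to)
    out <- states
    out[receives, ] <- upd[receives, , drop = FALSE]
    out
}

#' Neighbour-stage message passing
#'
#' Runs \code{rounds} QKV-attention rounds over the molecular bond graph:
#' each atom attends over its direct neighbours (attention weights
#' non-negative and summing to 1 per neighbour set), receives the
#' attention-weighted value message, and updates by residual add followed
#' by linear + ReLU. Isolated atoms pass through unchanged;
#' \code{rounds = 0} is the identity.
#'
#' @param states atom states from \code{\link{embedAtomsAndBonds}}.
#' @param graph the \linkS4class{MolecularGraph}.
#' @param params \code{\link{graphEncoderParams}}.
#' @param rounds number of rounds (default 3).
#' @return updated state matrix with \code{stage = "post-neighbour"}.
#' @export
neighbourMessageRounds <- function(states, graph, params, rounds = 3L) {
    if (rounds < 0L) stop("rounds must be non-negative")
    if (rounds > length(params$neighbour))
        stop("params provide only ", length(params$neighbour), " rounds")
    if (nrow(graph@edges)) {
        for (r in seq_len(rounds))
            states <- .attentionRound(states, graph@edges, params$neighbour[[r]])
    }
    attr(states, "stage") <- "post-neighbour"
    states
}

#' Superatom readout
#'
#' Adds a virtual superatom connected to every real atom (initialized as
#' the mean of the atom states), runs \code{rounds} further attention
#' rounds on the augmented graph (real atoms keep their bonds and
#' additionally exchange messages with the superatom), and maps the final
#' superatom state through a small FNN to the molecular representation.
#'
#' @param states atom states from \code{\link{neighbourMessageRounds}}.
#' @param graph the \linkS4class{MolecularGraph}.
#' @param params \code{\link{graphEncoderParams}}.
#' @param rounds superatom-stage rounds (default 3).
#' @return numeric vector of length \code{stateDim} (default 50).
#' @export
superatomReadout <- function(states, graph, params, rounds = 3L) {
    if (rounds < 0L) stop("rounds must be non-negative")
    if (rounds > length(params$super))
        stop("params provide only ", length(params$super), " rounds")
    n <- nrow(states)
    if (n < 1L) stop("empty molecule")
    aug <- rbind(states, colMeans(states))
    s <- n + 1L
    edges <- rbind(graph@edges,
                   cbind(seq_len(n), rep(s, n)),
                   cbind(rep(s, n), seq_len(n)))
    for (r in seq_len(rounds))
        aug <- .attentionRound(aug, edges, params$super[[r]])
    as.numeric(.mlpForward(params$final, aug[s, , drop = FALSE])$out)
}

#' Encode molecules into fixed-length representations
#'
#' Full graph-encoder pipeline (pre-embedding, neighbour rounds, superatom
#' readout). The representation is invariant to atom relabelling and can
#' replace raw inputs as the x fed to a neural process.
#'
#' @param graphs a \linkS4class{MolecularGraph} or list of them.
#' @param params \code{\link{graphEncoderParams}}.
#' @return numeric matrix (molecules x stateDim).
#' @export
encodeMolecules <- function(graphs, params = graphEncoderParams()) {
    if (is(graphs, "MolecularGraph")) graphs <- list(graphs)
    r <- params$config$rounds
    t(vapply(graphs, function(g) {
        st <- embedAtomsAndBonds(g, params)
        st <- neighbourMessageRounds(st, g, params, r)
        superatomReadout(st, g, params, r)
    }, numeric(params$config$stateDim)))
}

#' Attention weights of one neighbour round
#'
#' Diagnostic accessor: the attention coefficients each atom places on its
#' neighbours in the first neighbour round (non-negative, summing to 1 per
#' receiving atom).
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param params \code{\link{graphEncoderParams}}.
#' @return data frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
attentionWeights <- function(graph, params = graphEncoderParams()) {
    states <- embedAtomsAndBonds(graph, params)
    edges <- graph@edges
    if (!nrow(edges))
        return(data.frame(from = integer(0), to = integer(0),
                          weight = numeric(0)))
    w <- params$neighbour[[1]]
    from <- edges[, 1]; to <- edges[, 2]
    Q <- sweep(states %*% w$Wq, 2, w$bq, "+")
    K <- sweep(states %*% w$Wk, 2, w$bk, "+")
    logit <- rowSums(Q[to, , drop = FALSE] * K[from, , drop = FALSE]) /
        sqrt(ncol(states))
    mx <- tapply(logit, to, max)
    ex <- exp(logit - mx[as.character(to)])
    denom <- tapply(ex, to, sum)
    data.frame(from = from, to = to,
               weight = as.numeric(ex / denom[as.character(to)]))
}

#' Directional-gradient diagnostic for the graph encoder
#'
#' Checks that the encoder output depends on every parameter group at the
#' given parameters (no dead subnetwork): for each group, perturbs the
#' parameters along a random direction and measures the central-difference
#' directional derivative of a scalar readout (the sum of the molecular
#' representation over a batch of graphs).
#'
#' @param params \code{\link{graphEncoderParams}}.
#' @param graphs list of \linkS4class{MolecularGraph}s.
#' @param h finite-difference step (default 1e-4).
#' @param seed RNG seed for the directions.
#' @return named numeric vector of |directional derivative| per group.
#' @export
graphEncoderGradientFlow <- function(params, graphs, h = 1e-4, seed = 1L) {
    set.seed(seed)
    score <- function(p) sum(encodeMolecules(graphs, p))
    groups <- setdiff(names(params), "config")
    out <- vapply(groups, function(g) {
        dir <- rapply(params[[g]], function(x) stats::rnorm(length(x)),
                      how = "replace")
        shift <- function(p, s) {
            p[[g]] <- mapLeaves(p[[g]], dir, function(x, d) x + s * h * d)
            p
        }
        (score(shift(params, 1)) - score(shift(params, -1))) / (2 * h)
    }, numeric(1))
    abs(out)
}

# elementwise combine of two parallel nested numeric lists
mapLeaves <- function(a, b, f) {
    if (is.list(a)) return(Map(function(x, y) mapLeaves(x, y, f), a, b))
    z <- f(a, as.numeric(b))
    if (is.matrix(a)) matrix(z, nrow(a)) else z
}
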