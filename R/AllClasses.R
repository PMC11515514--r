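#' @import methods
NULL

#' Binary circular fingerprints for a set of molecules
#'
#' Matrix-backed container for binary circular (Morgan-style) fingerprints.
#' Rows are molecules, columns are hashed bit positions. The folding length
#' (\code{nBits}) and neighbourhood \code{radius} are stored so that
#' fingerprints computed under different configurations cannot be compared
#' silently.
#'
#' @slot bits integer matrix (molecules x nBits) with entries in {0, 1}.
#' @slot nBits fingerprint length.
#' @slot radius circular neighbourhood radius.
#' @slot smiles source SMILES, one per row.
#' @export
setClass("Fingerprints",
    representation(bits = "matrix", nBits = "integer", radius = "integer",
                   smiles = "character"))

setValidity("Fingerprints", function(object) {
    b <- object@bits
    if (!is.numeric(b) && !is.integer(b)) return("bits must be a numeric matrix")
    if (ncol(b) != object@nBits) return("ncol(bits) != nBits")
    if (length(object@smiles) != nrow(b)) return("one SMILES per fingerprint row required")
    if (length(b) && !all(b %in% c(0L, 1L))) return("fingerprint entries must be 0/1")
    if (object@nBits < 1L) return("nBits must be positive")
    if (object@radius < 0L) return("radius must be non-negative")
    TRUE
})

setMethod("show", "Fingerprints", function(object) {
    cat(sprintf("Fingerprints: %d molecule(s), %d bits, radius %d\n",
                nrow(object@bits), object@nBits, object@radius))
    if (nrow(object@bits))
        cat(sprintf("  mean popcount %.1f\n", mean(rowSums(object@bits))))
})

#' Attributed heavy-atom molecular graph
#'
#' Heavy-atom connectivity graph with one-hot/real atom feature rows and
#' per-directed-edge bond feature rows. Hydrogens are implicit and encoded
#' as an atom-level neighbour count feature. The featurizer configuration
#' is carried along so that feature dimensions can be checked downstream.
#'
#' @slot nAtoms number of heavy atoms.
#' @slot atomFeatures numeric matrix nAtoms x dAtom.
#' @slot bondFeatures numeric matrix (#directed edges) x dBond.
#' @slot edges integer matrix (#directed edges) x 2: (from, to) atom indices.
#' @slot adjacency symmetric binary nAtoms x nAtoms matrix, zero diagonal.
#' @slot sourceSmiles the SMILES the graph was built from.
#' @slot featurizer list describing the featurizer configuration.
#' @export
setClass("MolecularGraph",
    representation(nAtoms = "integer", atomFeatures = "matrix",
                   bondFeatures = "matrix", edges = "matrix",
                   adjacency = "matrix", sourceSmiles = "character",
                   featurizer = "list"))

setValidity("MolecularGraph", function(object) {
    n <- object@nAtoms
    if (n < 1L) return("molecule must have at least one heavy atom")
    if (nrow(object@atomFeatures) != n) return("atomFeatures must have one row per atom")
    A <- object@adjacency
    if (!all(dim(A) == c(n, n))) return("adjacency must be nAtoms x nAtoms")
    if (any(A != t(A))) return("adjacency must be symmetric")
    if (any(diag(A) != 0)) return("adjacency diagonal must be zero")
    if (!all(A %in% c(0, 1))) return("adjacency must be binary")
    ne <- nrow(object@edges)
    if (nrow(object@bondFeatures) != ne) return("one bond feature row per directed edge required")
    if (sum(A) != ne) return("edge list and adjacency disagree")
    if (ne > 0) {
        if (any(object@edges < 1L) || any(object@edges > n)) return("edge indices out of range")
        if (any(A[object@edges] != 1)) return("edge list and adjacency disagree")
    }
    TRUE
})

setMethod("show", "MolecularGraph", function(object) {
    cat(sprintf("MolecularGraph: %s\n  %d heavy atoms, %d directed edges, dAtom=%d, dBond=%d\n",
                object@sourceSmiles, object@nAtoms, nrow(object@edges),
                ncol(object@atomFeatures), ncol(object@bondFeatures)))
})

#' Observations of a single task
#'
#' One meta-learning task (function): paired inputs and real-valued labels.
#' Inputs are stored as a numeric matrix with one row per observation
#' (fingerprint bits, graph-encoder representations, or raw real vectors).
#'
#' @slot x numeric matrix, one row per observation.
#' @slot y numeric labels, one per row of \code{x}.
#' @slot name optional task name.
#' @export
setClass("TaskObservations",
    representation(x = "matrix", y = "numeric", name = "character"))

setValidity("TaskObservations", function(object) {
    if (nrow(object@x) != length(object@y)) return("x and y lengths differ")
    if (nrow(object@x) < 1L) return("a task needs at least one observation")
    if (!all(is.finite(object@y))) return("labels must be finite")
    TRUE
})

setMethod("show", "TaskObservations", function(object) {
    nm <- if (length(object@name)) object@name else "<unnamed>"
    cat(sprintf("TaskObservations %s: O_i = %d points, input dim %d\n",
                nm, nrow(object@x), ncol(object@x)))
})

#' Gaussian predictive distribution over target points
#'
#' Per-target predictive mean and variance under the conditional-independence
#' assumption: the joint predictive factorizes over targets as independent
#' Gaussians.
#'
#' @slot mean predictive means, length T.
#' @slot variance strictly positive predictive variances, length T.
#' @export
setClass("PredictiveGaussian",
    representation(mean = "numeric", variance = "numeric"))

setValidity("PredictiveGaussian", function(object) {
    if (length(object@mean) != length(object@variance)) return("mean/variance lengths differ")
    if (!all(is.finite(object@mean)) || !all(is.finite(object@variance)))
        return("predictive moments must be finite")
    if (any(object@variance <= 0)) return("variances must be strictly positive")
    TRUE
})

setMethod("show", "PredictiveGaussian", function(object) {
    cat(sprintf("PredictiveGaussian: %d target(s)\n", length(object@mean)))
    if (length(object@mean))
        cat(sprintf("  mean in [%.3g, %.3g], variance in [%.3g, %.3g]\n",
                    min(object@mean), max(object@mean),
                    min(object@variance), max(object@variance)))
})

#' Neural process model
#'
#' A conditional (CNP) or latent (LNP) neural process: encoder network
#' h_theta mapping (x, y) context pairs to per-point encodings, mean
#' aggregation to a global function encoding r, and decoder network g_theta
#' mapping (r, x) to a Gaussian predictive mean and variance. The LNP adds a
#' latent path phi mapping r to a diagonal Gaussian over a latent z which is
#' decoded instead of r.
#'
#' @slot kind "CNP" or "LNP".
#' @slot layers named list of parameter groups ("encoder", "decoder", and for
#'   LNP "latent"), each a list of layers with weight matrix W and bias b.
#' @slot config architecture and featurizer configuration list.
#' @export
setClass("NPModel",
    representation(kind = "character", layers = "list", config = "list"))

setValidity("NPModel", function(object) {
    if (!object@kind %in% c("CNP", "LNP")) return("kind must be 'CNP' or 'LNP'")
    if (!all(c("encoder", "decoder") %in% names(object@layers)))
        return("layers must contain 'encoder' and 'decoder'")
    if (object@kind == "LNP" && is.null(object@layers$latent))
        return("LNP requires a 'latent' parameter group")
    if (object@kind == "CNP" && !is.null(object@layers$latent))
        return("CNP must not carry latent-path parameters")
    TRUE
})

setMethod("show", "NPModel", function(object) {
    np <- sum(vapply(unlist(object@layers, recursive = FALSE),
                     function(l) length(l$W) + length(l$b), numeric(1)))
    cat(sprintf("%s neural process: input dim %d, encoding dim %d, %s parameters\n",
                object@kind, object@config$dimX, object@config$rDim,
                format(np, big.mark = ",")))
})

#' Bayesian optimization trajectory
#'
#' Record of a batched screening run over a fixed candidate library:
#' evaluated molecules in order, their objective values, and the monotone
#' best-so-far curve (objectives are minimized).
#'
#' @slot iteration iteration index per evaluated candidate (0 = initial batch).
#' @slot index library index of each evaluated candidate.
#' @slot value objective value of each evaluated candidate.
#' @slot bestSoFar running minimum after each evaluation.
#' @slot config the BO configuration used.
#' @export
setClass("BOTrajectory",
    representation(iteration = "integer", index = "integer", value = "numeric",
                   bestSoFar = "numeric", config = "list"))

setValidity("BOTrajectory", function(object) {
    n <- length(object@index)
    if (length(object@value) != n || length(object@bestSoFar) != n ||
        length(object@iteration) != n) return("trajectory fields must be aligned")
    if (n > 1 && any(diff(object@bestSoFar) > 1e-12)) return("best-so-far must be non-increasing")
    if (anyDuplicated(object@index)) return("a candidate may be evaluated only once")
    TRUE
})

setMethod("show", "BOTrajectory", function(object) {
    cat(sprintf("BOTrajectory: %d evaluations, %d iterations, best objective %.4g\n",
                length(object@index), max(c(0L, object@iteration)),
                if (length(object@bestSoFar)) min(object@bestSoFar) else NA_real_))
})

# --- accessors -------------------------------------------------------------

#' @describeIn Fingerprints-class binary bit matrix accessor
#' @param object a Fingerprints object
#' @export
setGeneric("fpBits", function(object) standardGeneric("fpBits"))
#' @export
setMethod("fpBits", "Fingerprints", function(object) object@bits)

#' Number of observations of a task
#' @param object a TaskObservations object
#' @return integer O_i
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))
#' @export
setMethod("nObs", "TaskObservations", function(object) nrow(object@x))

#' @rdname taskAccessors
#' @param object a TaskObservations object
#' @export
setGeneric("taskX", function(object) standardGeneric("taskX"))
#' Task input and label accessors
#' @name taskAccessors
#' @export
setMethod("taskX", "TaskObservations", function(object) object@x)

#' @rdname taskAccessors
#' @export
setGeneric("taskY", function(object) standardGeneric("taskY"))
#' @rdname taskAccessors
#' @export
setMethod("taskY", "TaskObservations", function(object) object@y)

#' @rdname predictiveAccessors
#' @param object a PredictiveGaussian object
#' @export
setGeneric("predMean", function(object) standardGeneric("predMean"))
#' Predictive moment accessors
#' @name predictiveAccessors
#' @export
setMethod("predMean", "PredictiveGaussian", function(object) object@mean)

#' @rdname predictiveAccessors
#' @export
setGeneric("predVar", function(object) standardGeneric("predVar"))
#' @rdname predictiveAccessors
#' @export
setMethod("predVar", "PredictiveGaussian", function(object) object@variance)

#' Best-so-far curve of a BO trajectory
#' @param object a BOTrajectory object
#' @export
setGeneric("bestSoFar", function(object) standardGeneric("bestSoFar"))
#' @export
setMethod("bestSoFar", "BOTrajectory", function(object) object@bestSoFar)

# --- constructors ----------------------------------------------------------

#' Construct a TaskObservations object
#'
#' @param x numeric matrix (rows = observations) or vector (treated as a
#'   single-column matrix, the 1D-regression case).
#' @param y numeric labels.
#' @param name optional task name.
#' @return a \linkS4class{TaskObservations} object.
#' @export
taskObservations <- function(x, y, name = character(0)) {
    if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1)
    new("TaskObservations", x = x, y = as.numeric(y), name = as.character(name))
}

#' Construct a PredictiveGaussian
#' @param mean predictive means.
#' @param variance predictive variances (strictly positive).
#' @return a \linkS4class{PredictiveGaussian} object.
#' @export
predictiveGaussian <- function(mean, variance) {
    new("PredictiveGaussian", mean = as.numeric(mean), variance = as.numeric(variance))
}

#' Context or target set for a neural process
#'
#' Lightweight pairing of inputs with (optional) labels. Targets at
#' prediction time may omit \code{y}.
#'
#' @param x numeric matrix (rows = points) or vector for 1D inputs.
#' @param y labels, or NULL for unlabelled targets.
#' @return list with elements \code{x}, \code{y} and \code{size}.
#' @export
contextSet <- function(x, y = NULL) {
    if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1)
    if (!is.null(y)) {
        y <- as.numeric(y)
        if (length(y) != nrow(x)) stop("x and y lengths differ")
    }
    list(x = x, y = y, size = nrow(x))
}
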