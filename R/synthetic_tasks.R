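# Desk-scale meta-dataset generators (1D sinusoid families; synthetic
# molecular task families over fingerprints with tunable inter-task
# correlation), a reader/writer for DOCKSTRING-style score tables, and the
# correlation-based meta-test diagnostics.

#' Sinusoid task family
#'
#' Tasks of the form y = A sin(rho (x - B)) (+ Gaussian label noise), with
#' amplitude A and phase B drawn uniformly per task and a family-wide
#' frequency rho. Changing rho between meta-training and meta-testing
#' creates the frequency-shift generalization challenge.
#'
#' @param aRange amplitude interval (default [0.1, 5]).
#' @param bRange phase interval (default [0, pi]).
#' @param rho frequency (default 1).
#' @param noiseSd label noise standard deviation (default 0).
#' @param xRange input sampling interval (default [-5, 5]).
#' @return a list of class \code{"sinusoidFamily"}.
#' @export
sinusoidFamily <- function(aRange = c(0.1, 5), bRange = c(0, pi), rho = 1,
                           noiseSd = 0, xRange = c(-5, 5)) {
    if (diff(aRange) < 0 || diff(bRange) < 0 || diff(xRange) < 0)
        stop("ranges must be nonempty")
    if (noiseSd < 0) stop("noiseSd must be non-negative")
    structure(list(aRange = aRange, bRange = bRange, rho = rho,
                   noiseSd = noiseSd, xRange = xRange),
              class = "sinusoidFamily")
}

#' Sample one sinusoid task
#'
#' Draws A and B uniformly from the family's ranges, x uniformly over the
#' input interval, and y = A sin(rho (x - B)) + noise.
#'
#' @param family a \code{\link{sinusoidFamily}}.
#' @param nPoints number of observations (>= 1).
#' @return a \linkS4class{TaskObservations} with attributes \code{A} and
#'   \code{B}.
#' @export
sampleSinusoidTask <- function(family, nPoints = 100L) {
    if (nPoints < 1L) stop("nPoints must be at least 1")
    A <- stats::runif(1, family$aRange[1], family$aRange[2])
    B <- stats::runif(1, family$bRange[1], family$bRange[2])
    x <- stats::runif(nPoints, family$xRange[1], family$xRange[2])
    y <- A * sin(family$rho * (x - B)) +
        if (family$noiseSd > 0) stats::rnorm(nPoints, sd = family$noiseSd) else 0
    task <- taskObservations(x, y)
    attr(task, "A") <- A; attr(task, "B") <- B
    task
}

# --- synthetic molecule library --------------------------------------------

.FRAGMENTS <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCNCC1", "C1CCOC1",
                "c1ccsc1", "c1cc[nH]c1", "C1CCCC1")
.CHAIN_ATOMS <- c("C", "C", "C", "N", "O", "S")
.SUBST <- c("F", "Cl", "Br", "O", "N", "C", "C(=O)O", "C(=O)N", "C#N", "OC")

#' Generate a synthetic drug-like SMILES library
#'
#' Builds random but syntactically and chemically valid SMILES by chaining
#' aliphatic/heteroatom backbones with ring fragments and small
#' substituents. Every string is checked by the SMILES parser; duplicates
#' are removed. Intended to stand in for a screening library so molecular
#' tests and experiments need no external download (the generated molecules
#' are synthetic and simpler than real drug-like chemistry).
#'
#' @param n number of unique molecules requested.
#' @param seed RNG seed.
#' @return character vector of \code{n} unique SMILES.
#' @export
generateSmilesLibrary <- function(n, seed = 1L) {
    set.seed(seed)
    out <- character(0)
    guard <- 0L
    while (length(out) < n && guard < 50L * n) {
        guard <- guard + 1L
        nunit <- sample(2:5, 1)
        units <- character(nunit)
        for (u in seq_len(nunit)) {
            if (stats::runif(1) < 0.35) {
                frag <- sample(.FRAGMENTS, 1)
                # renumber ring digits so fragments can repeat in one SMILES
                units[u] <- gsub("1", as.character(u + 1L), frag, fixed = TRUE)
            } else {
                atom <- sample(.CHAIN_ATOMS, 1)
                sub <- if (atom == "C" && stats::runif(1) < 0.4)
                    paste0("(", sample(.SUBST, 1), ")") else ""
                units[u] <- paste0(atom, sub)
            }
        }
        smi <- paste(units, collapse = "")
        if (!smi %in% out && isValidSmilesSyntax(smi)) out <- c(out, smi)
    }
    if (length(out) < n)
        stop("could not generate ", n, " unique molecules")
    out
}

#' Specification of a synthetic molecular task family
#'
#' Labels of task i are a sparse linear function of fingerprint bits,
#' \code{y_i = (lambda w_shared + (1 - lambda) w_i) . fp + noise}: a shared
#' weight vector (common to all tasks) mixed with a task-specific one. The
#' mixing weight lambda in [0, 1] tunes the inter-task correlation
#' (lambda = 1: essentially identical tasks; lambda = 0: unrelated tasks),
#' emulating the spectrum of protein-target similarity in a docking-score
#' matrix.
#'
#' @param nTasks number of tasks.
#' @param lambda shared-weight fraction in [0, 1].
#' @param nActiveBits number of nonzero weights per weight vector.
#' @param noiseSd label noise standard deviation.
#' @param nBits fingerprint length used for the inputs.
#' @param radius fingerprint radius.
#' @param seed RNG seed.
#' @return a list of class \code{"synthMolTaskSpec"}.
#' @export
synthMolTaskSpec <- function(nTasks = 50L, lambda = 0.7, nActiveBits = 30L,
                             noiseSd = 0.3, nBits = 512L, radius = 2L,
                             seed = 1L) {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
    structure(list(nTasks = as.integer(nTasks), lambda = lambda,
                   nActiveBits = as.integer(nActiveBits), noiseSd = noiseSd,
                   nBits = as.integer(nBits), radius = as.integer(radius),
                   seed = as.integer(seed)),
              class = "synthMolTaskSpec")
}

#' Generate a synthetic molecular meta-dataset
#'
#' Fingerprints all molecules and creates one task per draw of the mixed
#' weight vector (see \code{\link{synthMolTaskSpec}}). Every task labels
#' every molecule (a complete molecules-by-tasks matrix, the DOCKSTRING
#' layout). Labels are standardized per task to zero mean, unit variance
#' before adding noise of sd \code{noiseSd} (so noise is on a comparable
#' scale across tasks).
#'
#' @param smiles character vector of molecules (>= 2) or a precomputed
#'   \linkS4class{Fingerprints} object.
#' @param spec a \code{\link{synthMolTaskSpec}}.
#' @return list with \code{tasks} (list of \linkS4class{TaskObservations}
#'   over identical inputs), \code{fingerprints}, and the label
#'   \code{matrix} (molecules x tasks).
#' @export
makeMolecularMetadataset <- function(smiles, spec = synthMolTaskSpec()) {
    fps <- if (is(smiles, "Fingerprints")) smiles
           else smilesToFingerprint(smiles, nBits = spec$nBits,
                                    radius = spec$radius)
    X <- fpBits(fps)
    if (nrow(X) < 2L) stop("need at least 2 molecules")
    set.seed(spec$seed)
    nb <- ncol(X)
    drawW <- function() {
        w <- numeric(nb)
        idx <- sample.int(nb, min(spec$nActiveBits, nb))
        w[idx] <- stats::rnorm(length(idx))
        w
    }
    wShared <- drawW()
    Y <- matrix(0, nrow(X), spec$nTasks)
    for (i in seq_len(spec$nTasks)) {
        w <- spec$lambda * wShared + (1 - spec$lambda) * drawW()
        raw <- as.numeric(X %*% w)
        s <- stats::sd(raw)
        if (s < 1e-12) raw <- raw + stats::rnorm(length(raw), sd = 1e-3)
        raw <- (raw - mean(raw)) / max(stats::sd(raw), 1e-12)
        Y[, i] <- raw + if (spec$noiseSd > 0)
            stats::rnorm(length(raw), sd = spec$noiseSd) else 0
    }
    colnames(Y) <- sprintf("task%03d", seq_len(spec$nTasks))
    tasks <- lapply(seq_len(spec$nTasks), function(i)
        taskObservations(X, Y[, i], name = colnames(Y)[i]))
    list(tasks = tasks, fingerprints = fps, matrix = Y)
}

# --- DOCKSTRING-style tables ----------------------------------------------

#' Read a DOCKSTRING-style score table
#'
#' Tab-separated with a header: a SMILES column, an optional split column
#' (values "train"/"test"), and one numeric column per target. The score
#' matrix must be complete; rows with missing or non-numeric scores raise
#' an error naming the row and column (or are dropped under
#' \code{missing = "drop"}). Duplicate SMILES are rejected.
#'
#' @param path file path.
#' @param smilesColumn name of the SMILES column (default "smiles").
#' @param splitColumn name of the split column, or NULL if absent
#'   (default "split" when present).
#' @param missing "error" (default) or "drop" for rows with missing scores.
#' @return list of class \code{"dockstringMatrix"}: \code{smiles},
#'   \code{targets}, \code{scores} (molecules x targets), \code{split}
#'   (factor or NULL), preserving row order.
#' @export
readDockstringTable <- function(path, smilesColumn = "smiles",
                                splitColumn = NULL,
                                missing = c("error", "drop")) {
    missing <- match.arg(missing)
    # comment.char must be off: "#" is a SMILES bond symbol
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            comment.char = "", quote = "")
    if (!smilesColumn %in% names(df))
        stop("missing SMILES column '", smilesColumn, "' in header")
    if (is.null(splitColumn) && "split" %in% names(df)) splitColumn <- "split"
    targetCols <- setdiff(names(df), c(smilesColumn, splitColumn))
    if (!length(targetCols)) stop("no target score columns found")
    smiles <- as.character(df[[smilesColumn]])
    dup <- duplicated(smiles)
    if (any(dup)) stop("duplicate SMILES at row(s): ",
                       paste(which(dup), collapse = ", "))
    scores <- matrix(NA_real_, nrow(df), length(targetCols),
                     dimnames = list(NULL, targetCols))
    for (tc in targetCols) {
        v <- df[[tc]]
        num <- suppressWarnings(as.numeric(v))
        badNum <- !is.na(v) & v != "" & is.na(num)
        if (any(badNum))
            stop("non-numeric score in column '", tc, "', row(s) ",
                 paste(which(badNum), collapse = ", "))
        scores[, tc] <- num
    }
    bad <- which(rowSums(is.na(scores)) > 0)
    if (length(bad)) {
        if (missing == "error") {
            col <- colnames(scores)[which(is.na(scores[bad[1], ]))[1]]
            stop("missing score at row ", bad[1], ", column '", col,
                 "' (use missing = \"drop\" to drop incomplete rows)")
        }
        scores <- scores[-bad, , drop = FALSE]
        smiles <- smiles[-bad]
        if (!is.null(splitColumn)) df <- df[-bad, , drop = FALSE]
    }
    split <- if (!is.null(splitColumn)) factor(df[[splitColumn]]) else NULL
    structure(list(smiles = smiles, targets = targetCols, scores = scores,
                   split = split),
              class = "dockstringMatrix")
}

#' Write a DOCKSTRING-style score table
#' @param mat a \code{"dockstringMatrix"} (as from
#'   \code{\link{readDockstringTable}} or built in code).
#' @param path output path (TSV).
#' @export
writeDockstringTable <- function(mat, path) {
    df <- data.frame(smiles = mat$smiles, check.names = FALSE)
    if (!is.null(mat$split)) df$split <- as.character(mat$split)
    for (tc in mat$targets) df[[tc]] <- mat$scores[, tc]
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Maximum inter-target Pearson correlation
#'
#' For each target, the maximum Pearson correlation of its score column
#' with any other target's. High values mean the target has a close
#' relative among the other tasks (an easy meta-test candidate); low values
#' flag divergent targets. Pairs involving a constant column are skipped
#' with a warning.
#'
#' @param mat a \code{"dockstringMatrix"}, or a numeric molecules-x-targets
#'   matrix with column names.
#' @return named numeric vector, one value per target.
#' @export
targetMaxCorrelation <- function(mat) {
    scores <- if (inherits(mat, "dockstringMatrix")) mat$scores else mat
    if (ncol(scores) < 2L) stop("need at least 2 targets")
    if (nrow(scores) < 3L) stop("need at least 3 molecules")
    sds <- apply(scores, 2, stats::sd)
    if (any(sds == 0))
        warning("constant column(s) skipped: ",
                paste(colnames(scores)[sds == 0], collapse = ", "))
    cm <- suppressWarnings(stats::cor(scores))
    diag(cm) <- NA
    cm[sds == 0, ] <- NA; cm[, sds == 0] <- NA
    out <- apply(cm, 2, function(col)
        if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
    stats::setNames(out, colnames(scores))
}

#' Few-shot-learning split of a score matrix
#'
#' Partitions targets into meta-training (ftrain = everything else) and
#' meta-testing (ftest = \code{metaTestTargets}), and samples disjoint
#' molecule sets dtrain/dtest from the rows carrying the corresponding
#' split labels (the scaffold split is consumed, not computed). Contexts
#' for meta-test tasks are drawn from ftest x dtrain; evaluation happens on
#' ftest x dtest.
#'
#' @param mat a \code{"dockstringMatrix"} with a split factor.
#' @param metaTestTargets character vector of meta-test target names.
#' @param nDtrain,nDtest molecules to sample from the train/test split rows.
#' @param seed RNG seed.
#' @return list with \code{ftrain}, \code{ftest} (target names) and
#'   \code{dtrain}, \code{dtest} (row indices into the matrix).
#' @export
makeFslSplit <- function(mat, metaTestTargets, nDtrain, nDtest, seed = 1L) {
    stopifnot(inherits(mat, "dockstringMatrix"))
    if (is.null(mat$split)) stop("matrix has no split labels")
    if (!all(metaTestTargets %in% mat$targets))
        stop("unknown meta-test target(s): ",
             paste(setdiff(metaTestTargets, mat$targets), collapse = ", "))
    trainRows <- which(mat$split == "train")
    testRows <- which(mat$split == "test")
    if (length(trainRows) < nDtrain)
        stop("only ", length(trainRows), " train-split rows, need ", nDtrain)
    if (length(testRows) < nDtest)
        stop("only ", length(testRows), " test-split rows, need ", nDtest)
    set.seed(seed)
    list(ftrain = setdiff(mat$targets, metaTestTargets),
         ftest = metaTestTargets,
         dtrain = sort(sample(trainRows, nDtrain)),
         dtest = sort(sample(testRows, nDtest)))
}

#' Tasks from a score matrix restricted to selected rows
#'
#' Convenience builder turning columns of a (DOCKSTRING-style or synthetic)
#' score matrix into \linkS4class{TaskObservations} over given inputs.
#'
#' @param X numeric input matrix (molecules x features), aligned with the
#'   score matrix rows.
#' @param scores molecules x targets score matrix.
#' @param targets target names to keep (default: all columns).
#' @param rows row indices to keep (default: all rows).
#' @return list of \linkS4class{TaskObservations}.
#' @export
tasksFromScores <- function(X, scores, targets = colnames(scores),
                            rows = seq_len(nrow(scores))) {
    lapply(targets, function(tc)
        taskObservations(X[rows, , drop = FALSE], scores[rows, tc], name = tc))
}
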