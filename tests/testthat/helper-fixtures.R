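# Shared fixtures: tiny models, random context/target sets, and graph
# permutation utilities used across test files.

tinyModel <- function(kind = "CNP", dimX = 2L, seed = 1L) {
    npModel(kind, dimX = dimX, hidden = 8L, rDim = 6L, zDim = 4L,
            latentHidden = 5L, seed = seed)
}

randomSet <- function(n, d = 2L, labelled = TRUE) {
    contextSet(matrix(stats::rnorm(n * d), n),
               if (labelled) stats::rnorm(n) else NULL)
}

permuteSet <- function(set, perm) {
    contextSet(set$x[perm, , drop = FALSE],
               if (!is.null(set$y)) set$y[perm] else NULL)
}

# relabel the atoms of a MolecularGraph with a permutation
permuteGraph <- function(graph, perm) {
    inv <- order(perm)   # inv[old] = new position
    edges <- graph@edges
    newEdges <- cbind(inv[edges[, 1]], inv[edges[, 2]])
    ord <- order(newEdges[, 1], newEdges[, 2])
    new("MolecularGraph",
        nAtoms = graph@nAtoms,
        atomFeatures = graph@atomFeatures[perm, , drop = FALSE],
        bondFeatures = graph@bondFeatures[ord, , drop = FALSE],
        edges = matrix(as.integer(newEdges[ord, ]), ncol = 2),
        adjacency = graph@adjacency[perm, perm],
        sourceSmiles = graph@sourceSmiles,
        featurizer = graph@featurizer)
}

# central finite-difference gradient of a scalar loss at selected coords.
# Coordinates whose finite-difference estimate is unstable across step
# sizes (a ReLU kink sits inside the stencil) are reported as NA so the
# caller can exclude them from the comparison.
numGrad <- function(lossFn, model, group, layer, field, coords, h = 1e-6) {
    fd <- function(k, hh) {
        mp <- model; mp@layers[[group]][[layer]][[field]][k] <-
            mp@layers[[group]][[layer]][[field]][k] + hh
        mm <- model; mm@layers[[group]][[layer]][[field]][k] <-
            mm@layers[[group]][[layer]][[field]][k] - hh
        (lossFn(mp) - lossFn(mm)) / (2 * hh)
    }
    vapply(coords, function(k) {
        g1 <- fd(k, h); g2 <- fd(k, h * 10)
        if (abs(g1 - g2) > 1e-3 * max(1, abs(g1))) NA_real_ else g1
    }, numeric(1))
}

FIXTURE_SMILES <- c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "CCN(CC)CC",
                    "C1CCNCC1", "c1ccncc1", "CC(C)Cc1ccc(C)cc1", "OCC(O)CO",
                    "CSCC", "FC(F)F")
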