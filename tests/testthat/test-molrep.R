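test_that("fingerprints are deterministic, binary and sized as configured", {
    fp <- smilesToFingerprint(c("CCO", "CCO", "c1ccccc1"), nBits = 1024L,
                              radius = 3L)
    b <- fpBits(fp)
    expect_equal(dim(b), c(3L, 1024L))
    expect_true(all(b %in% c(0L, 1L)))
    expect_gt(sum(b[1, ]), 0)
    expect_identical(b[1, ], b[2, ])
    # different molecules land on different bit sets
    expect_false(identical(b[1, ], b[3, ]))
    # parameters are carried along
    expect_identical(fp@nBits, 1024L)
    expect_identical(fp@radius, 3L)
})

test_that("malformed SMILES raise invalid-input errors naming the input", {
    expect_error(smilesToFingerprint("C("), "C\\(")
    expect_error(smilesToGraph("[NaCl"), "NaCl")
    expect_error(smilesToGraph("C1CC"), "invalid")
})

test_that("graph featurization matches molecule structure", {
    g <- smilesToGraph("C")
    expect_identical(g@nAtoms, 1L)
    expect_identical(nrow(g@edges), 0L)
    # n-H one-hot block (columns 13..19 = 0..6 hydrogens) peaks at 4
    expect_equal(unname(which(g@atomFeatures[1, 13:19] == 1)) - 1L, 4L)

    benz <- smilesToGraph("c1ccccc1")
    expect_identical(benz@nAtoms, 6L)
    expect_identical(nrow(benz@edges), 12L)
    expect_true(all(benz@atomFeatures[, "aromatic"] == 1))
    expect_true(all(benz@atomFeatures[, "inRing"] == 1))
    expect_true(validObject(benz))
    # adjacency symmetric with zero diagonal is enforced by the class
    expect_equal(benz@adjacency, t(benz@adjacency))
    expect_equal(diag(benz@adjacency), rep(0, 6))
})

test_that("featurizer dimensions are constant across molecules", {
    gs <- smilesToGraph(FIXTURE_SMILES)
    dAtoms <- vapply(gs, function(g) ncol(g@atomFeatures), integer(1))
    dBonds <- vapply(gs, function(g) ncol(g@bondFeatures), integer(1))
    expect_identical(unique(dAtoms), 44L)
    expect_identical(unique(dBonds), 10L)
    # configuration is serialized with the output
    expect_identical(gs[[1]]@featurizer$dAtom, 44L)
})

test_that("canonical and non-canonical SMILES give isomorphic graphs", {
    pairs <- list(c("c1ccccc1O", "Oc1ccccc1"),
                  c("CCO", "OCC"),
                  c("CC(=O)O", "OC(C)=O"))
    for (p in pairs) {
        g1 <- smilesToGraph(p[1]); g2 <- smilesToGraph(p[2])
        expect_identical(g1@nAtoms, g2@nAtoms)
        expect_identical(nrow(g1@edges), nrow(g2@edges))
        # same multiset of atom feature rows
        key <- function(g) sort(apply(g@atomFeatures, 1, paste, collapse = ","))
        expect_identical(key(g1), key(g2))
    }
})

test_that("tanimoto matches the set formula, is symmetric and bounded", {
    mk <- function(on, n = 16) { v <- numeric(n); v[on] <- 1; v }
    expect_identical(tanimoto(mk(1:3), mk(2:4)), 0.5)
    expect_identical(tanimoto(mk(1:5), mk(1:5)), 1.0)
    expect_identical(tanimoto(mk(1:3), mk(5:8)), 0.0)
    expect_identical(tanimoto(mk(integer(0)), mk(integer(0))), 1.0)
    expect_error(tanimoto(mk(1, 8), mk(1, 16)), "lengths differ")
    set.seed(42)
    for (i in 1:25) {
        a <- rbinom(32, 1, 0.3); b <- rbinom(32, 1, 0.3)
        s <- tanimoto(a, b)
        onA <- which(a == 1); onB <- which(b == 1)
        ref <- if (!length(union(onA, onB))) 1 else
            length(intersect(onA, onB)) / length(union(onA, onB))
        expect_equal(s, ref, tolerance = 1e-12)
        expect_equal(s, tanimoto(b, a))
        expect_true(s >= 0 && s <= 1)
    }
})

test_that("max similarity to reference finds exact matches and ignores order", {
    fp <- smilesToFingerprint(FIXTURE_SMILES[1:5], nBits = 512L, radius = 2L)
    b <- fpBits(fp)
    sims <- maxSimilarityToReference(b, b[c(3, 1), ])
    expect_equal(sims[1], 1.0)
    expect_equal(sims[3], 1.0)
    expect_equal(maxSimilarityToReference(b[4, , drop = FALSE],
                                          b[2, , drop = FALSE])[1],
                 tanimoto(b[4, ], b[2, ]))
    shuffled <- maxSimilarityToReference(b, b[c(1, 3), ])
    expect_equal(sims, shuffled)
    expect_error(maxSimilarityToReference(b, b[integer(0), , drop = FALSE]),
                 "empty")
})

test_that("graph and fingerprint contracts agree with an independent toolkit", {
    script <- '
import json, sys
from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger
RDLogger.DisableLog("rdApp.*")
out = {}
m = Chem.MolFromSmiles("c1ccccc1")
out["benz"] = [m.GetNumAtoms(), m.GetNumBonds(),
               all(a.GetIsAromatic() for a in m.GetAtoms())]
mm = Chem.MolFromSmiles("C")
out["methane"] = [mm.GetNumAtoms(), mm.GetAtomWithIdx(0).GetTotalNumHs()]
fp = AllChem.GetMorganFingerprintAsBitVect(Chem.MolFromSmiles("CCO"), 3, nBits=1024)
out["cco_popcount"] = fp.GetNumOnBits()
out["bad"] = Chem.MolFromSmiles("C(") is None
print(json.dumps(out))
'
    res <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                    stdout = TRUE, stderr = FALSE))
    skip_if(length(res) == 0 || !nzchar(res[length(res)]),
            "python toolkit oracle unavailable")
    oracle <- jsonlite::fromJSON(res[length(res)])
    benz <- smilesToGraph("c1ccccc1")
    expect_identical(benz@nAtoms, as.integer(oracle$benz[[1]]))
    expect_identical(nrow(benz@edges), 2L * as.integer(oracle$benz[[2]]))
    expect_true(as.logical(oracle$benz[[3]]))
    g <- smilesToGraph("C")
    expect_identical(g@nAtoms, as.integer(oracle$methane[[1]]))
    expect_equal(unname(which(g@atomFeatures[1, 13:19] == 1)) - 1L,
                 as.integer(oracle$methane[[2]]))
    # popcount positive in both dialects (bit indices are toolkit-specific)
    expect_gt(oracle$cco_popcount, 0)
    expect_gt(sum(fpBits(smilesToFingerprint("CCO", 1024L, 3L))), 0)
    expect_true(oracle$bad)
    expect_error(smilesToFingerprint("C("))
})

test_that("SMILES can be read from plain text and from tabular columns", {
    plain <- tempfile(fileext = ".txt")
    writeLines(c("CCO", "c1ccccc1", ""), plain)
    expect_identical(readSmiles(plain), c("CCO", "c1ccccc1"))
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("smiles\tscore", "CCO\t-1.2", "CCN\t-0.5"), tsv)
    expect_identical(readSmiles(tsv, column = "smiles"), c("CCO", "CCN"))
    expect_error(readSmiles(tsv, column = "nope"), "not found")
})
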