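test_that("sinusoid tasks follow A sin(rho (x - B)) within their bounds", {
    fam <- sinusoidFamily(aRange = c(1, 1), bRange = c(0, 0), rho = 1)
    set.seed(1)
    tk <- sampleSinusoidTask(fam, 50)
    x <- taskX(tk)[, 1]
    expect_equal(taskY(tk), sin(x), tolerance = 1e-12)
    # exact point: A=1, B=0, x = pi/2 gives y = 1
    expect_equal(1 * sin(1 * (pi / 2 - 0)), 1, tolerance = 1e-15)
    fam2 <- sinusoidFamily(noiseSd = 0.1)
    set.seed(2)
    for (i in 1:10) {
        tk2 <- sampleSinusoidTask(fam2, 100)
        expect_true(all(abs(taskY(tk2)) <= abs(attr(tk2, "A")) + 5 * 0.1))
    }
    set.seed(7); a <- sampleSinusoidTask(fam2, 20)
    set.seed(7); b <- sampleSinusoidTask(fam2, 20)
    expect_identical(taskX(a), taskX(b))
    expect_identical(taskY(a), taskY(b))
})

test_that("lambda controls inter-task correlation of molecular tasks", {
    smiles <- generateSmilesLibrary(120, seed = 5)
    fps <- smilesToFingerprint(smiles, nBits = 256L, radius = 2L)
    hi <- makeMolecularMetadataset(fps, synthMolTaskSpec(nTasks = 8,
        lambda = 1, noiseSd = 0, nBits = 256L, seed = 3))
    cors <- stats::cor(hi$matrix)[upper.tri(diag(8))]
    expect_true(all(cors >= 0.999))
    lo <- makeMolecularMetadataset(fps, synthMolTaskSpec(nTasks = 8,
        lambda = 0, noiseSd = 0, nBits = 256L, seed = 3))
    expect_lt(mean(abs(stats::cor(lo$matrix)[upper.tri(diag(8))])), 0.25)
    # reproducible under the same seed
    hi2 <- makeMolecularMetadataset(fps, synthMolTaskSpec(nTasks = 8,
        lambda = 1, noiseSd = 0, nBits = 256L, seed = 3))
    expect_identical(hi$matrix, hi2$matrix)
    # every task labels every molecule (complete matrix)
    expect_identical(dim(hi$matrix), c(120L, 8L))
    expect_identical(nObs(hi$tasks[[1]]), 120L)
})

test_that("max inter-target correlation rises with lambda", {
    smiles <- generateSmilesLibrary(100, seed = 6)
    fps <- smilesToFingerprint(smiles, nBits = 256L, radius = 2L)
    med <- function(lambda) {
        m <- makeMolecularMetadataset(fps, synthMolTaskSpec(nTasks = 6,
            lambda = lambda, noiseSd = 0.1, nBits = 256L, seed = 4))
        stats::median(targetMaxCorrelation(m$matrix))
    }
    v <- c(med(0), med(0.5), med(0.9))
    expect_true(all(diff(v) > 0))
})

test_that("dockstring tables round-trip and reject bad input", {
    # "#" (triple bond) must not be treated as a comment character
    smiles <- c("CC(C#N)O", "CCN", "c1ccccc1")
    mat <- structure(list(smiles = smiles, targets = c("T1", "T2"),
                          scores = matrix(c(-1.5, -2, -3, 0.5, 1, 2), 3,
                                          dimnames = list(NULL, c("T1", "T2"))),
                          split = factor(c("train", "train", "test"))),
                     class = "dockstringMatrix")
    path <- tempfile(fileext = ".tsv")
    writeDockstringTable(mat, path)
    back <- readDockstringTable(path)
    expect_identical(back$smiles, smiles)
    expect_identical(back$targets, c("T1", "T2"))
    expect_equal(back$scores, mat$scores)
    expect_identical(as.character(back$split), as.character(mat$split))

    lines <- readLines(path)
    lines[3] <- "CCN\ttrain\t\t1"   # blank a score cell
    bad <- tempfile(fileext = ".tsv"); writeLines(lines, bad)
    expect_error(readDockstringTable(bad), "row 2.*T1")
    dropped <- readDockstringTable(bad, missing = "drop")
    expect_identical(dropped$smiles, c("CC(C#N)O", "c1ccccc1"))

    lines2 <- readLines(path)
    lines2[3] <- "CC(C#N)O\ttrain\t-2\t1"  # duplicate SMILES
    dup <- tempfile(fileext = ".tsv"); writeLines(lines2, dup)
    expect_error(readDockstringTable(dup), "duplicate")

    lines3 <- readLines(path)
    lines3[4] <- "c1ccccc1\ttest\tnot_a_number\t2"
    nn <- tempfile(fileext = ".tsv"); writeLines(lines3, nn)
    expect_error(readDockstringTable(nn), "non-numeric.*T1")
})

test_that("target max correlation handles duplicates, negations, constants", {
    set.seed(8)
    a <- rnorm(60)
    m <- cbind(A = a, B = a, C = rnorm(60))
    mc <- targetMaxCorrelation(m)
    expect_equal(unname(mc["A"]), 1, tolerance = 1e-12)
    expect_equal(unname(mc["B"]), 1, tolerance = 1e-12)
    expect_lt(unname(mc["C"]), 0.5)
    # a column and its negation: with an independent third column the max
    # for the negated pair is the (small) correlation with the third
    m2 <- cbind(A = a, nA = -a, C = rnorm(60))
    mc2 <- targetMaxCorrelation(m2)
    expect_equal(unname(mc2["A"]), unname(stats::cor(a, m2[, "C"])),
                 tolerance = 1e-12)
    expect_equal(unname(mc2["nA"]), unname(-stats::cor(a, m2[, "C"])),
                 tolerance = 1e-12)
    expect_warning(mc3 <- targetMaxCorrelation(cbind(A = a, K = rep(1, 60))),
                   "constant")
    expect_true(is.na(mc3["K"]))
})

test_that("fsl splits partition targets and keep molecule sets disjoint", {
    smiles <- sprintf("C%s", strrep("C", 1:40))
    mat <- structure(list(
        smiles = smiles, targets = c("T1", "T2", "T3", "T4"),
        scores = matrix(rnorm(160), 40,
                        dimnames = list(NULL, c("T1", "T2", "T3", "T4"))),
        split = factor(rep(c("train", "test"), each = 20))),
        class = "dockstringMatrix")
    sp <- makeFslSplit(mat, c("T2"), nDtrain = 15, nDtest = 10, seed = 3)
    expect_setequal(c(sp$ftrain, sp$ftest), mat$targets)
    expect_length(intersect(sp$ftrain, sp$ftest), 0)
    expect_length(intersect(sp$dtrain, sp$dtest), 0)
    expect_true(all(mat$split[sp$dtrain] == "train"))
    expect_true(all(mat$split[sp$dtest] == "test"))
    sp2 <- makeFslSplit(mat, c("T2"), nDtrain = 15, nDtest = 10, seed = 3)
    expect_identical(sp, sp2)
    expect_error(makeFslSplit(mat, "T9", 5, 5), "unknown")
    expect_error(makeFslSplit(mat, "T1", 30, 5), "train-split rows")
})

test_that("the generated library is parseable, unique and fingerprintable", {
    smi <- generateSmilesLibrary(60, seed = 9)
    expect_length(unique(smi), 60)
    fp <- smilesToFingerprint(smi, nBits = 256L, radius = 2L)
    expect_true(all(rowSums(fpBits(fp)) > 0))
    expect_identical(generateSmilesLibrary(60, seed = 9), smi)
})
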