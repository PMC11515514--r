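# Molecular featurization: SMILES -> binary circular fingerprints and
# attributed heavy-atom graphs, plus Tanimoto similarity utilities.
# SMILES parsing, ring and aromaticity perception are delegated to
# ChemmineR/ChemmineOB (OpenBabel backend); OpenBabel is lenient with
# malformed SMILES, so a syntactic validator enforces error contracts first.

.ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B", "Si")
.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1,
                      I = 1, P = 3, B = 3, Si = 4)
# atomic mass, Van der Waals radius (A), covalent radius (A)
.ATOM_PROPS <- matrix(c(
    12.011, 1.70, 0.76,   # C
    14.007, 1.55, 0.71,   # N
    15.999, 1.52, 0.66,   # O
    32.06,  1.80, 1.05,   # S
    18.998, 1.47, 0.57,   # F
    35.45,  1.75, 1.02,   # Cl
    79.904, 1.85, 1.20,   # Br
    126.90, 1.98, 1.39,   # I
    30.974, 1.80, 1.07,   # P
    10.81,  1.92, 0.84,   # B
    28.085, 2.10, 1.11,   # Si
    50.0,   1.80, 1.20),  # other (generic)
    ncol = 3, byrow = TRUE,
    dimnames = list(c(.ELEMENTS, "other"), c("mass", "vdw", "covalent")))

#' Check SMILES syntax
#'
#' Lightweight syntactic validation: balanced parentheses and brackets, no
#' empty branches, paired ring-closure digits, and a legal token alphabet.
#' This guards the featurizers against silently accepting malformed input.
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, TRUE where the string is syntactically plausible.
#' @export
isValidSmilesSyntax <- function(smiles) {
    vapply(smiles, function(s) {
        if (is.na(s) || !nzchar(s)) return(FALSE)
        chars <- strsplit(s, "")[[1]]
        if (!all(grepl("[][A-Za-z0-9@+()=#$:/\\\\%.*-]", chars))) return(FALSE)
        depth <- 0L
        for (ch in chars) {
            if (ch == "(") depth <- depth + 1L
            if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
        }
        if (depth != 0L) return(FALSE)
        brk <- cumsum((chars == "[") - (chars == "]"))
        if (any(brk > 1L) || any(brk < 0L) || brk[length(brk)] != 0L) return(FALSE)
        if (grepl("\\(\\)", s)) return(FALSE)
        if (grepl("\\[\\]", s)) return(FALSE)
        # ring-closure labels must come in pairs (outside bracket atoms)
        nobrk <- gsub("\\[[^]]*\\]", "A", s)
        nobrk <- gsub("%([0-9]{2})", " \\1 ", nobrk)   # two-digit closures
        digits <- c(regmatches(nobrk, gregexpr("(?<![0-9])[0-9](?![0-9])", nobrk, perl = TRUE))[[1]],
                    regmatches(nobrk, gregexpr(" [0-9]{2} ", nobrk))[[1]])
        if (length(digits)) {
            tab <- table(trimws(digits))
            if (any(tab %% 2 != 0)) return(FALSE)
        }
        TRUE
    }, logical(1), USE.NAMES = FALSE)
}

.requireChemmine <- function() {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
        stop("ChemmineOB is required for SMILES parsing")
}

# Parse a vector of SMILES into plain-R molecule descriptions:
# list(elements, charge, nH, degree, bonds = matrix(a1, a2, order, stereo),
#      inRing, aromaticAtom, aromaticBond, hybrid)
.parseSmiles <- function(smiles) {
    .requireChemmine()
    bad <- !isValidSmilesSyntax(smiles)
    if (any(bad))
        stop("invalid SMILES: ", paste(smiles[bad], collapse = ", "))
    nm <- sprintf("m%d", seq_along(smiles))
    sdfs <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, nm)))
    lapply(seq_along(smiles), function(i) .parseOne(sdfs[[i]], smiles[i]))
}

.parseOne <- function(sdf, smi) {
    cl <- ChemmineR::header(sdf)[["Counts_Line"]]
    nAtoms <- suppressWarnings(as.integer(substr(cl, 1, 3)))
    if (is.na(nAtoms) || nAtoms < 1L)
        stop("SMILES has no heavy atoms or failed to parse: ", smi)
    if (nAtoms == 1L) return(.parseSingleAtom(smi))

    ab <- ChemmineR::atomblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    chgcode <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nAtoms)
    charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                `6` = -2, `7` = -3)[as.character(chgcode)]
    charge[is.na(charge)] <- 0
    parity <- if ("C7" %in% colnames(ab)) ab[, "C7"] else rep(0, nAtoms)

    bb <- ChemmineR::bondblock(sdf)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
    nBonds <- if (ncol(bb) >= 4 && nrow(bb) && any(bb[, 1] > 0)) nrow(bb) else 0L
    bonds <- if (nBonds) cbind(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                               order = as.integer(bb[, 3]),
                               stereo = as.integer(bb[, 4]))
             else matrix(integer(0), ncol = 4,
                         dimnames = list(NULL, c("a1", "a2", "order", "stereo")))

    inRing <- rep(FALSE, nAtoms)
    aromaticAtom <- rep(FALSE, nAtoms)
    aromaticBond <- rep(FALSE, nBonds)
    ringBond <- rep(FALSE, nBonds)
    rng <- tryCatch(ChemmineR::rings(sdf, upper = 14, type = "all", arom = TRUE),
                    error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    if (length(rng$RINGS)) {
        bondKey <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
        for (k in seq_along(rng$RINGS)) {
            idx <- as.integer(sub("^.*_", "", rng$RINGS[[k]]))
            inRing[idx] <- TRUE
            nxt <- c(idx[-1], idx[1])
            key <- paste(pmin(idx, nxt), pmax(idx, nxt))
            hit <- bondKey %in% key
            ringBond <- ringBond | hit
            if (isTRUE(rng$AROMATIC[[k]])) {
                aromaticAtom[idx] <- TRUE
                aromaticBond <- aromaticBond | hit
            }
        }
    }

    degree <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = nAtoms)
    boSum <- rep(0L, nAtoms)
    nDouble <- rep(0L, nAtoms)
    nTriple <- rep(0L, nAtoms)
    if (nBonds) for (b in seq_len(nBonds)) {
        i <- bonds[b, 1]; j <- bonds[b, 2]; o <- bonds[b, 3]
        boSum[i] <- boSum[i] + o; boSum[j] <- boSum[j] + o
        if (o == 2L) { nDouble[i] <- nDouble[i] + 1L; nDouble[j] <- nDouble[j] + 1L }
        if (o == 3L) { nTriple[i] <- nTriple[i] + 1L; nTriple[j] <- nTriple[j] + 1L }
    }
    defv <- .DEFAULT_VALENCE[elements]
    defv[is.na(defv)] <- 0
    nH <- pmax(0L, as.integer(defv + charge - boSum))

    hybrid <- ifelse(nTriple > 0 | nDouble >= 2, "sp",
              ifelse(nDouble > 0 | aromaticAtom, "sp2",
              ifelse(degree >= 6, "sp3d2", ifelse(degree == 5, "sp3d", "sp3"))))

    list(elements = elements, charge = charge, nH = nH, degree = degree,
         bonds = bonds, inRing = inRing, aromaticAtom = aromaticAtom,
         aromaticBond = aromaticBond, ringBond = ringBond,
         hybrid = hybrid, chiral = parity != 0, smiles = smi)
}

# ChemmineR's SDF container mangles single-atom molecules; read the two
# fixed-width fields (element, charge code) from the molfile line instead.
.parseSingleAtom <- function(smi) {
    .requireChemmine()
    txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"))
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    atomLine <- lines[5]
    element <- trimws(substr(atomLine, 32, 34))
    chgcode <- suppressWarnings(as.integer(trimws(substr(atomLine, 37, 39))))
    charge <- c(0, 3, 2, 1, 0, -1, -2, -3)[chgcode + 1L]
    if (is.na(charge)) charge <- 0
    defv <- .DEFAULT_VALENCE[element]
    if (is.na(defv)) defv <- 0
    list(elements = element, charge = charge,
         nH = max(0L, as.integer(defv + charge)), degree = 0L,
         bonds = matrix(integer(0), ncol = 4,
                        dimnames = list(NULL, c("a1", "a2", "order", "stereo"))),
         inRing = FALSE, aromaticAtom = FALSE, aromaticBond = logical(0),
         ringBond = logical(0), hybrid = "sp3", chiral = FALSE, smiles = smi)
}

.oneHot <- function(value, levels) {
    m <- matrix(0, length(value), length(levels))
    idx <- match(value, levels)
    idx[is.na(idx)] <- length(levels)   # last level is the overflow/other bin
    m[cbind(seq_along(value), idx)] <- 1
    m
}

.featurizerConfig <- function() {
    list(elements = c(.ELEMENTS, "other"),
         hybrid = c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other"),
         countCap = 6L, charges = c(-2, -1, 0, 1, 2, NA),
         bondTypes = c("single", "double", "triple", "aromatic"),
         stereo = c("none", "up", "down", "other"),
         dAtom = 44L, dBond = 10L)
}

.atomFeatureMatrix <- function(mol) {
    cfg <- .featurizerConfig()
    cap <- function(v) pmin(v, cfg$countCap)
    el <- .oneHot(mol$elements, cfg$elements)
    nh <- .oneHot(cap(mol$nH), 0:cfg$countCap)
    dg <- .oneHot(cap(mol$degree), 0:cfg$countCap)
    ch <- .oneHot(mol$charge, c(-2, -1, 0, 1, 2, 99))
    hy <- .oneHot(mol$hybrid, cfg$hybrid)
    props <- .ATOM_PROPS[ifelse(mol$elements %in% rownames(.ATOM_PROPS),
                                mol$elements, "other"), , drop = FALSE]
    cbind(el, nh, dg, ch, hy,
          inRing = as.numeric(mol$inRing),
          aromatic = as.numeric(mol$aromaticAtom),
          chiral = as.numeric(mol$chiral),
          mass = unname(props[, "mass"]) / 100,
          vdw = unname(props[, "vdw"]),
          covalent = unname(props[, "covalent"]))
}

.bondFeatureRow <- function(order, aromatic, inRing, stereo) {
    type <- if (aromatic) "aromatic" else
            c("single", "double", "triple")[min(order, 3)]
    cfg <- .featurizerConfig()
    tfeat <- as.numeric(cfg$bondTypes == type)
    sfeat <- as.numeric(cfg$stereo == c("none", "up", "other", "other", "other",
                                        "other", "down")[min(stereo, 6) + 1L])
    c(tfeat, conjugated = NA_real_, inRing = as.numeric(inRing), sfeat)
}

#' Convert SMILES to an attributed heavy-atom graph
#'
#' Parses a SMILES string and builds a \linkS4class{MolecularGraph} over
#' heavy atoms only (hydrogens become an atom-level count feature). Atom
#' features are one-hot blocks for element, hydrogen-neighbour count,
#' heavy-neighbour count, formal charge, hybridisation, ring membership,
#' aromaticity and chirality, plus atomic mass and Van der Waals / covalent
#' radii as real scalars. Bond features (per directed edge) are a bond-type
#' one-hot (single / double / triple / aromatic), conjugation and ring
#' flags, and a stereo one-hot.
#'
#' @param smiles a single SMILES string, or a character vector.
#' @return a \linkS4class{MolecularGraph}, or a list of them when
#'   \code{length(smiles) > 1}.
#' @examples
#' \dontrun{
#' g <- smilesToGraph("c1ccccc1")
#' }
#' @export
smilesToGraph <- function(smiles) {
    mols <- .parseSmiles(smiles)
    out <- lapply(mols, .graphFromMol)
    if (length(out) == 1L) out[[1]] else out
}

.graphFromMol <- function(mol) {
    n <- length(mol$elements)
    atomF <- .atomFeatureMatrix(mol)
    adj <- matrix(0, n, n)
    nb <- nrow(mol$bonds)
    edges <- matrix(integer(0), ncol = 2)
    bondF <- matrix(numeric(0), ncol = .featurizerConfig()$dBond)
    if (nb) {
        # conjugated: both endpoints carry a multiple/aromatic bond
        multi <- mol$bonds[, "order"] >= 2 | mol$aromaticBond
        touch <- rep(FALSE, n)
        touch[mol$bonds[multi, 1]] <- TRUE
        touch[mol$bonds[multi, 2]] <- TRUE
        rows <- vector("list", nb)
        el <- matrix(integer(0), ncol = 2)
        for (b in seq_len(nb)) {
            i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
            adj[i, j] <- 1; adj[j, i] <- 1
            f <- .bondFeatureRow(mol$bonds[b, "order"], mol$aromaticBond[b],
                                 mol$ringBond[b], mol$bonds[b, "stereo"])
            f[5] <- as.numeric(touch[i] && touch[j])
            rows[[b]] <- rbind(f, f)
            el <- rbind(el, c(i, j), c(j, i))
        }
        bondF <- do.call(rbind, rows)
        rownames(bondF) <- NULL
        edges <- el
    }
    new("MolecularGraph", nAtoms = as.integer(n), atomFeatures = atomF,
        bondFeatures = bondF, edges = matrix(as.integer(edges), ncol = 2),
        adjacency = adj, sourceSmiles = mol$smiles,
        featurizer = .featurizerConfig())
}

# --- circular fingerprints -------------------------------------------------

.HASH_MOD <- 2147483647
.hashInts <- function(h, values) {
    for (v in values) h <- (h * 7927 + v + 1) %% .HASH_MOD
    h
}

#' Convert SMILES to binary circular fingerprints
#'
#' Computes hashed circular (Morgan-style) substructure fingerprints: each
#' atom's neighbourhood of radius 0..\code{radius} is summarized by an
#' integer invariant (seeded from element, degree, H count, charge, ring and
#' aromaticity flags, then iteratively combined with sorted neighbour
#' invariants and bond orders) and folded into \code{nBits} positions.
#' Deterministic: identical SMILES and parameters give identical bits.
#'
#' @param smiles character vector of SMILES.
#' @param nBits fingerprint length (default 1024).
#' @param radius circular neighbourhood radius (default 3).
#' @return a \linkS4class{Fingerprints} object with one row per SMILES.
#' @export
smilesToFingerprint <- function(smiles, nBits = 1024L, radius = 3L) {
    nBits <- as.integer(nBits); radius <- as.integer(radius)
    if (nBits < 1L) stop("nBits must be positive")
    if (radius < 0L) stop("radius must be non-negative")
    mols <- .parseSmiles(smiles)
    bits <- t(vapply(mols, function(mol) .circularBits(mol, nBits, radius),
                     integer(nBits)))
    new("Fingerprints", bits = bits, nBits = nBits, radius = radius,
        smiles = as.character(smiles))
}

.circularBits <- function(mol, nBits, radius) {
    n <- length(mol$elements)
    cfg <- .featurizerConfig()
    inv <- vapply(seq_len(n), function(a)
        .hashInts(17, c(match(mol$elements[a], cfg$elements, nomatch = 12L),
                        mol$degree[a], mol$nH[a], mol$charge[a] + 10,
                        as.integer(mol$inRing[a]),
                        as.integer(mol$aromaticAtom[a]))), numeric(1))
    seen <- inv
    if (radius > 0 && nrow(mol$bonds)) {
        nbrs <- lapply(seq_len(n), function(a) {
            hit <- mol$bonds[, 1] == a | mol$bonds[, 2] == a
            b <- mol$bonds[hit, , drop = FALSE]
            ar <- mol$aromaticBond[hit]
            other <- ifelse(b[, 1] == a, b[, 2], b[, 1])
            list(other = other, code = ifelse(ar, 4L, b[, "order"]))
        })
        for (r in seq_len(radius)) {
            inv <- vapply(seq_len(n), function(a) {
                nb <- nbrs[[a]]
                if (!length(nb$other)) return(.hashInts(inv[a], c(r)))
                pair <- nb$code * .HASH_MOD + inv[nb$other]
                ord <- order(pair)
                .hashInts(inv[a], c(r, as.vector(rbind(nb$code[ord],
                                                       inv[nb$other][ord]))))
            }, numeric(1))
            seen <- c(seen, inv)
        }
    }
    out <- integer(nBits)
    out[(seen %% nBits) + 1] <- 1L
    out
}

# --- Tanimoto utilities ----------------------------------------------------

.bitsOf <- function(fp, what = "fingerprint") {
    if (is(fp, "Fingerprints")) return(fp@bits)
    if (is.matrix(fp)) return(fp)
    if (is.numeric(fp) || is.logical(fp)) return(matrix(as.numeric(fp), nrow = 1))
    stop("cannot interpret ", what, " of class ", class(fp)[1])
}

#' Tanimoto similarity between two fingerprints
#'
#' \code{|on(a) & on(b)| / |on(a) | on(b)|}. Two all-zero fingerprints are
#' defined to have similarity 1 (identical empty bit sets), preserving the
#' rule that identical inputs have similarity 1.
#'
#' @param a,b single fingerprints: 1-row \linkS4class{Fingerprints} objects
#'   or binary vectors of equal length.
#' @return similarity in [0, 1]; symmetric in its arguments.
#' @export
tanimoto <- function(a, b) {
    va <- as.numeric(.bitsOf(a)[1, ]); vb <- as.numeric(.bitsOf(b)[1, ])
    if (length(va) != length(vb)) stop("fingerprint lengths differ")
    inter <- sum(va * vb)
    uni <- sum(va) + sum(vb) - inter
    if (uni == 0) 1.0 else inter / uni
}

# cross-similarity matrix between two binary matrices (rows = molecules)
.tanimotoCross <- function(A, B) {
    A <- .bitsOf(A); B <- .bitsOf(B)
    if (ncol(A) != ncol(B)) stop("fingerprint lengths differ")
    inter <- A %*% t(B)
    uni <- outer(rowSums(A), rowSums(B), "+") - inter
    out <- ifelse(uni == 0, 1, inter / pmax(uni, 1e-300))
    out
}

#' Maximum Tanimoto similarity of queries to a reference set
#'
#' For each query fingerprint, the similarity to its closest neighbour in
#' the reference set. \code{1 - maxSimilarityToReference(...)} is the
#' Tanimoto distance used for applicability-domain bucketing.
#'
#' @param queries query fingerprints (\linkS4class{Fingerprints} or binary matrix).
#' @param reference nonempty reference fingerprints.
#' @return numeric vector, one maximum similarity per query.
#' @export
maxSimilarityToReference <- function(queries, reference) {
    R <- .bitsOf(reference, "reference")
    if (nrow(R) == 0L) stop("reference set is empty")
    sims <- .tanimotoCross(.bitsOf(queries, "queries"), R)
    apply(sims, 1, max)
}

#' Read SMILES from a text file
#'
#' Accepts either plain text with one SMILES per line, or a delimited table
#' (TSV/CSV, autodetected from the header line) with a named SMILES column.
#'
#' @param path file path.
#' @param column column name holding SMILES when the file is tabular;
#'   NULL (default) for one-per-line plain text.
#' @return character vector of SMILES.
#' @export
readSmiles <- function(path, column = NULL) {
    if (is.null(column)) {
        out <- readLines(path, warn = FALSE)
        return(trimws(out[nzchar(trimws(out))]))
    }
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            comment.char = "", quote = "")
    if (!column %in% names(df))
        stop("column '", column, "' not found in ", path)
    as.character(df[[column]])
}
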