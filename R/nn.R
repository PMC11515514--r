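# Internal fully-connected network machinery with hand-derived gradients.
# Layers are lists(W, b); ReLU on hidden layers, linear output layer.
# Gradients are verified against central finite differences in the tests.

.heInit <- function(dims) {
    lapply(seq_len(length(dims) - 1L), function(l) {
        fanIn <- dims[l]
        list(W = matrix(stats::rnorm(fanIn * dims[l + 1L], sd = sqrt(2 / fanIn)),
                        fanIn, dims[l + 1L]),
             b = numeric(dims[l + 1L]))
    })
}

.mlpForward <- function(layers, X) {
    L <- length(layers)
    H <- vector("list", L + 1L); Z <- vector("list", L)
    H[[1L]] <- X
    for (l in seq_len(L)) {
        Z[[l]] <- sweep(H[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
        H[[l + 1L]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
    }
    list(out = H[[L + 1L]], H = H, Z = Z)
}

.mlpBackward <- function(layers, fw, dOut) {
    L <- length(layers)
    grads <- vector("list", L)
    dH <- dOut
    for (l in rev(seq_len(L))) {
        dZ <- if (l < L) dH * (fw$Z[[l]] > 0) else dH
        grads[[l]] <- list(W = unname(crossprod(fw$H[[l]], dZ)),
                           b = unname(colSums(dZ)))
        dH <- tcrossprod(dZ, layers[[l]]$W)
    }
    list(grads = grads, dX = dH)
}

.zeroLike <- function(layers) {
    lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

.addGrads <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    Map(function(x, y) list(W = x$W + y$W, b = x$b + y$b), a, b)
}

.scaleGrads <- function(g, s) {
    lapply(g, function(l) list(W = l$W * s, b = l$b * s))
}

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
.sigmoid <- function(x) 1 / (1 + exp(-x))

# --- Adam ------------------------------------------------------------------

.adamInit <- function(groups) {
    lapply(groups, function(layers)
        lapply(layers, function(l)
            list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)))
}

.gradGlobalNorm <- function(grads, mask) {
    s <- 0
    for (g in names(grads)) for (l in seq_along(grads[[g]])) {
        if (!mask[[g]][l]) next
        s <- s + sum(grads[[g]][[l]]$W^2) + sum(grads[[g]][[l]]$b^2)
    }
    sqrt(s)
}

# One Adam step over named parameter groups; layers where mask is FALSE are
# left bitwise untouched (their optimizer state does not advance either).
.adamStep <- function(layers, grads, state, t, lr, clip = 10,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, mask = NULL) {
    if (is.null(mask))
        mask <- lapply(layers, function(g) rep(TRUE, length(g)))
    gn <- .gradGlobalNorm(grads, mask)
    sc <- if (is.finite(gn) && gn > clip) clip / gn else 1
    for (g in names(layers)) {
        for (l in seq_along(layers[[g]])) {
            if (!mask[[g]][l]) next
            gW <- grads[[g]][[l]]$W * sc; gb <- grads[[g]][[l]]$b * sc
            st <- state[[g]][[l]]
            st$mW <- beta1 * st$mW + (1 - beta1) * gW
            st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
            st$mb <- beta1 * st$mb + (1 - beta1) * gb
            st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
            c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
            layers[[g]][[l]]$W <- layers[[g]][[l]]$W -
                lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
            layers[[g]][[l]]$b <- layers[[g]][[l]]$b -
                lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
            state[[g]][[l]] <- st
        }
    }
    list(layers = layers, state = state)
}
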