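# Compact seeded feed-forward network: ReLU hidden layers, softmax
# output, full-batch Adam on cross-entropy. Sized by `hidden` (the
# workflow default is 500/200/10). Deterministic under the seed; a fixed
# iteration budget with a loss-based early stop keeps training bounded.

mlpFit <- function(x, y, hidden = c(500L, 200L, 10L), maxIter = 150L,
                   lr = 1e-3, seed = 1L, tol = 1e-5) {
    stopifnot(is.matrix(x), is.factor(y), nlevels(y) >= 2L)
    set.seed(seed)
    sizes <- c(ncol(x), hidden, nlevels(y))
    nL <- length(sizes) - 1L
    W <- vector("list", nL); b <- vector("list", nL)
    for (l in seq_len(nL)) {
        W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                      sd = sqrt(2 / sizes[l])),
                         sizes[l], sizes[l + 1L])
        b[[l]] <- rep(0, sizes[l + 1L])
    }
    Y <- diag(nlevels(y))[as.integer(y), , drop = FALSE]
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mB <- lapply(b, function(v) v * 0); vB <- mB
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    n <- nrow(x); prevLoss <- Inf
    for (it in seq_len(maxIter)) {
        a <- vector("list", nL + 1L); a[[1L]] <- x
        for (l in seq_len(nL)) {
            z <- sweep(a[[l]] %*% W[[l]], 2L, b[[l]], `+`)
            a[[l + 1L]] <- if (l < nL) pmax(z, 0) else z
        }
        zo <- a[[nL + 1L]]
        zo <- zo - apply(zo, 1L, max)
        P <- exp(zo); P <- P / rowSums(P)
        loss <- -mean(log(rowSums(P * Y) + 1e-12))
        if (abs(prevLoss - loss) < tol && it > 10L) break
        prevLoss <- loss
        delta <- (P - Y) / n
        for (l in rev(seq_len(nL))) {
            gW <- crossprod(a[[l]], delta)
            gB <- colSums(delta)
            if (l > 1L)
                delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
            mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
            vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
            mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
            vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
            cr <- lr * sqrt(1 - b2^it) / (1 - b1^it)
            W[[l]] <- W[[l]] - cr * mW[[l]] / (sqrt(vW[[l]]) + eps)
            b[[l]] <- b[[l]] - cr * mB[[l]] / (sqrt(vB[[l]]) + eps)
        }
    }
    structure(list(W = W, b = b, levels = levels(y)), class = "cfMLP")
}

mlpProb <- function(fit, x) {
    a <- x
    nL <- length(fit$W)
    for (l in seq_len(nL)) {
        z <- sweep(a %*% fit$W[[l]], 2L, fit$b[[l]], `+`)
        a <- if (l < nL) pmax(z, 0) else z
    }
    a <- a - apply(a, 1L, max)
    P <- exp(a); P <- P / rowSums(P)
    colnames(P) <- fit$levels
    P
}
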