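## small builders shared across test files

## CountMatrix from a samples x taxa matrix given as rows
cm <- function(...) CountMatrix(rbind(...), samplesAsRows = TRUE)

## a reproducible small random count table (no zeros guaranteed)
randomCounts <- function(I = 8, J = 12, lambda = 5, seed = 1) {
    set.seed(seed)
    CountMatrix(matrix(rpois(I * J, lambda), I, J))
}

## a SimDraw built by hand (bypasses drawEffects)
manualDraw <- function(a, t, bVec = numeric(length(t)),
                       x = rep(c(0, 1), each = length(a) / 2), g = 1) {
    methods::new("SimDraw", a = a, t = t, bVec = bVec, x = as.numeric(x), g = g)
}

## brute-force between-group share of total column variance: the
## independent oracle for the RDA constrained fraction with binary x
bruteForceBetweenFraction <- function(M, x) {
    M <- sweep(M, 2, colMeans(M))
    between <- 0
    for (j in seq_len(ncol(M))) {
        for (grp in unique(x)) {
            idx <- x == grp
            between <- between + sum(idx) * mean(M[idx, j])^2
        }
    }
    between / sum(M^2)
}

## independent loop-level Bayesian-multiplicative replacement with a
## geometric-mean prior (the oracle for gbmImpute)
gbmOracle <- function(Y, onProportions = FALSE, strength = 1) {
    n <- rowSums(Y)
    p <- Y / n
    gm <- numeric(ncol(Y))
    for (j in seq_len(ncol(Y))) {
        obs <- p[, j][p[, j] > 0]
        gm[j] <- exp(mean(log(obs)))
    }
    tj <- gm / sum(gm)
    out <- p
    for (i in seq_len(nrow(Y))) {
        zero <- Y[i, ] == 0
        repl <- tj * strength / (n[i] + strength)
        out[i, zero] <- repl[zero]
        out[i, !zero] <- p[i, !zero] * (1 - sum(repl[zero]))
    }
    if (onProportions) out else out * n
}
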