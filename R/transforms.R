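#' Pseudo-counted natural log of a count table
#'
#' `L = log(Y + pseudo)` elementwise. Adding the pseudo-count to every cell
#' (the common convention) preserves zeroes as `log(pseudo)` but destroys
#' the exact proportionality to the library size that makes log-ratios
#' total-free; this is the root of the library-size leakage the diagnostics
#' detect.
#'
#' @param Y a [CountMatrix-class] or numeric samples-by-taxa matrix.
#' @param pseudo positive pseudo-count (default 1).
#' @return numeric samples-by-taxa matrix.
#' @examples
#' logPseudo(rbind(c(0, 3)))  # 0, log(4)
#' @export
logPseudo <- function(Y, pseudo = 1) {
    if (pseudo <= 0) stop("pseudo must be > 0")
    log(.smat(Y) + pseudo)
}

#' Double-centre a log count matrix
#'
#' Computes `S[i,j] = L[i,j] - r[i] - c[j] + m` with `r` the row means, `c`
#' the column means and `m` the grand mean of `L`. Equivalent to a clr
#' transform (row centring) followed by column centring; the input to
#' log-ratio PCA.
#'
#' @param L numeric samples-by-taxa matrix (typically from [logPseudo()]).
#' @param pseudoCount scalar recorded in the result for provenance.
#' @return a [CenteredLogMatrix-class].
#' @examples
#' doubleCenter(rbind(c(0, 2), c(4, 2)))  # S = [[-1, 1], [1, -1]]
#' @export
doubleCenter <- function(L, pseudoCount = NA_real_) {
    L <- as.matrix(L)
    if (length(L) == 0) stop("empty matrix")
    r <- rowMeans(L)
    cc <- colMeans(L)
    m <- mean(L)
    S <- L - outer(r, cc, "+") + m
    methods::new("CenteredLogMatrix", S = S, r = unname(r), c = unname(cc),
                 grandMean = m, pseudoCount = as.numeric(pseudoCount))
}

#' Log-ratio (double-centred log) matrix of a count table
#'
#' Shorthand for `doubleCenter(logPseudo(Y, pseudo))`.
#'
#' @inheritParams logPseudo
#' @return a [CenteredLogMatrix-class].
#' @export
logRatioMatrix <- function(Y, pseudo = 1) {
    doubleCenter(logPseudo(Y, pseudo), pseudoCount = pseudo)
}

#' @describeIn CenteredLogMatrix the double-centred matrix S
#'   (samples x taxa).
#' @export
setMethod("centeredMatrix", "CenteredLogMatrix", function(x) x@S)

#' @describeIn CenteredLogMatrix the per-sample means r of the log matrix.
#' @export
setMethod("logRowMeans", "CenteredLogMatrix", function(x) x@r)

#' @describeIn CenteredLogMatrix the per-taxon means c of the log matrix.
#' @export
setMethod("logColMeans", "CenteredLogMatrix", function(x) x@c)

#' @describeIn CenteredLogMatrix the grand mean of the log matrix.
#' @export
setMethod("grandMean", "CenteredLogMatrix", function(x) x@grandMean)

setMethod("show", "CenteredLogMatrix", function(object) {
    cat("CenteredLogMatrix:", nrow(object@S), "samples x", ncol(object@S),
        "taxa\n")
    cat(sprintf("  r range: %.3f - %.3f; grand mean %.3f; pseudo-count %s\n",
        min(object@r), max(object@r), object@grandMean,
        format(object@pseudoCount)))
})

#' Centred log-ratio transform with pseudo-count
#'
#' `clr(Y)[i, ] = log(Y[i, ] + pseudo) - mean(log(Y[i, ] + pseudo))`,
#' i.e. the log matrix minus its row means, identical to the classical clr
#' of `Y + pseudo`. For zero-free rows the result is invariant to scaling
#' the row by a constant; rows containing zeroes lose that invariance under
#' pseudo-counting, which is precisely how the library size re-enters the
#' transformed data.
#'
#' @inheritParams logPseudo
#' @param pseudo nonnegative pseudo-count; `0` is allowed only for zero-free
#'   tables.
#' @return numeric samples-by-taxa matrix with zero row means.
#' @examples
#' clr(rbind(c(0, 3)))  # -log(2), +log(2)
#' @export
clr <- function(Y, pseudo = 1) {
    m <- .smat(Y)
    if (pseudo < 0) stop("pseudo must be >= 0")
    if (pseudo == 0 && any(m == 0))
        stop("pseudo = 0 requires a zero-free table")
    L <- log(m + pseudo)
    L - rowMeans(L)
}

#' Geometric Bayesian-multiplicative (GBM) zero imputation
#'
#' Replaces zero counts with positive estimates from a Bayesian-
#' multiplicative treatment of the multinomial zeros under a Dirichlet
#' prior whose expectation is taken from the data: the prior proportion of
#' taxon j is the geometric mean of its observed (nonzero) proportions
#' across samples, normalized over taxa. For sample i with library size
#' `n_i` and prior strength `s_i = strength`, a zero cell gets the replaced
#' proportion `t_j * s_i / (n_i + s_i)`, and the observed cells of the row
#' are shrunk by the common factor `1 - sum(replaced)`, so the ratios among
#' observed taxa are preserved (the multiplicative property).
#'
#' @param Y a [CountMatrix-class] or nonnegative samples-by-taxa matrix;
#'   every row and every column must contain at least one nonzero.
#' @param onProportions logical; if `TRUE` the result rows are closed to
#'   sum 1, otherwise the replaced proportions are rescaled to the original
#'   library sizes (row sums preserved).
#' @param strength positive prior strength `s_i` (one value recycled over
#'   samples). The exact strength used with amplicon data varies between
#'   implementations; it is exposed here rather than fixed.
#' @return strictly positive numeric samples-by-taxa matrix.
#' @examples
#' gbmImpute(rbind(c(0, 5, 5), c(2, 4, 4)))
#' @export
gbmImpute <- function(Y, onProportions = FALSE, strength = 1) {
    m <- .smat(Y)
    if (any(m < 0)) stop("counts must be nonnegative")
    n <- rowSums(m)
    if (any(n == 0)) stop("all-zero row: cannot impute")
    if (any(colSums(m) == 0)) stop("all-zero column: prior undefined")
    if (strength <= 0) stop("strength must be > 0")
    p <- m / n
    ## prior proportions: normalized geometric mean of observed proportions
    gm <- apply(p, 2, function(z) exp(mean(log(z[z > 0]))))
    tj <- gm / sum(gm)
    s <- rep_len(strength, nrow(m))
    zero <- m == 0
    repl <- outer(s / (n + s), tj)      # candidate replacement proportions
    shrink <- 1 - rowSums(repl * zero)  # mass taken from observed cells
    out <- p * shrink
    out[zero] <- repl[zero]
    if (any(out <= 0)) stop("imputation produced non-positive proportions")
    if (!onProportions) out <- out * n
    dimnames(out) <- dimnames(p)
    out
}

#' Log proportions transform
#'
#' `log((Y[i,j] + pseudo) / n_i)` with `n_i` the library size of sample i.
#' Columns are centred downstream by the ordination, not here.
#'
#' @inheritParams logPseudo
#' @return numeric samples-by-taxa matrix.
#' @examples
#' logProportions(rbind(c(0, 3)))  # log(1/3), log(4/3)
#' @export
logProportions <- function(Y, pseudo = 1) {
    m <- .smat(Y)
    n <- rowSums(m)
    if (any(n == 0)) stop("zero library size")
    if (pseudo <= 0) stop("pseudo must be > 0")
    log((m + pseudo) / n)
}

#' Elementwise square root of a count table
#'
#' The usual variance-stabilizing companion of correspondence analysis on
#' overdispersed counts.
#'
#' @inheritParams logPseudo
#' @return numeric samples-by-taxa matrix.
#' @export
sqrtTransform <- function(Y) {
    sqrt(.smat(Y))
}
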