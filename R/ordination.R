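#' Log-ratio principal component analysis
#'
#' Singular value decomposition `S = U diag(d) t(V)` of the double-centred
#' log matrix, with no column rescaling: the squared-loading contribution
#' diagnostic is meaningful only on the unscaled matrix, and centring-only
#' is equivalent to PCA on the pre-centred input. Per-axis explained
#' inertia is `d_k^2 / sum(d^2)` with the denominator over all singular
#' values.
#'
#' @param S a [CenteredLogMatrix-class] or numeric matrix (samples x taxa).
#' @param K number of axes to retain; defaults to `min(I - 1, J - 1)` (the
#'   maximal rank after double centring).
#' @return an [OrdinationResult-class].
#' @examples
#' S <- doubleCenter(rbind(c(0, 2), c(4, 2)))
#' singularValues(lrPCA(S))  # 2
#' @export
lrPCA <- function(S, K = NULL) {
    M <- if (methods::is(S, "CenteredLogMatrix")) S@S else as.matrix(S)
    I <- nrow(M); J <- ncol(M)
    maxK <- max(1L, min(I - 1L, J - 1L))
    if (is.null(K)) K <- maxK
    K <- as.integer(K)
    if (K < 1L || K > min(I, J))
        stop(sprintf("K must lie in [1, %d]", min(I, J)))
    dec <- svd(M)
    tot <- sum(dec$d^2)
    expl <- if (tot > 0) dec$d^2 / tot else rep(0, length(dec$d))
    U <- dec$u[, seq_len(K), drop = FALSE]
    V <- dec$v[, seq_len(K), drop = FALSE]
    rownames(U) <- rownames(M)
    rownames(V) <- colnames(M)
    colnames(U) <- colnames(V) <- paste0("Axis", seq_len(K))
    methods::new("OrdinationResult", U = U, V = V, d = dec$d[seq_len(K)],
                 explainedFraction = expl[seq_len(K)], totalInertia = tot,
                 K = K)
}

#' @describeIn OrdinationResult sample scores U (orthonormal columns).
#' @export
setMethod("sampleScores", "OrdinationResult", function(x) x@U)

#' @describeIn OrdinationResult taxon loadings V (orthonormal columns).
#' @export
setMethod("taxonLoadings", "OrdinationResult", function(x) x@V)

#' @describeIn OrdinationResult singular values, nonincreasing.
#' @export
setMethod("singularValues", "OrdinationResult", function(x) x@d)

#' @describeIn OrdinationResult per-axis fraction of total inertia.
#' @export
setMethod("explainedFraction", "OrdinationResult", function(x)
    x@explainedFraction)

setMethod("show", "OrdinationResult", function(object) {
    cat("OrdinationResult:", nrow(object@U), "samples,", nrow(object@V),
        "taxa,", object@K, "axes\n")
    k <- min(object@K, 5L)
    cat("  explained fraction:",
        paste(sprintf("%.3f", object@explainedFraction[seq_len(k)]),
              collapse = " "),
        if (object@K > k) "...\n" else "\n")
})

## centred design matrix from a vector, factor or matrix
.designMatrix <- function(x, n) {
    if (is.factor(x) || is.character(x))
        x <- stats::model.matrix(~ factor(x))[, -1, drop = FALSE]
    x <- as.matrix(x)
    if (nrow(x) != n) stop("explanatory variable length does not match rows")
    xc <- sweep(x, 2, colMeans(x))
    if (all(abs(xc) < 1e-12)) stop("constant explanatory variable")
    xc
}

#' Redundancy analysis: constrained-inertia fraction and axes
#'
#' Projects the (column-centred) response matrix onto the span of the
#' centred explanatory design, `Mhat = H M`, and returns the constrained
#' fraction `||Mhat||_F^2 / ||M||_F^2` together with the SVD of the fitted
#' matrix. With a single binary explanatory variable this equals the
#' between-group share of the total variance.
#'
#' @param M numeric samples-by-taxa matrix or [CenteredLogMatrix-class].
#'   Columns are centred before projection (a no-op for double-centred
#'   input).
#' @param x explanatory variable: numeric vector, factor, or design matrix
#'   with one row per sample. Must not be constant.
#' @return list with `constrainedFraction` (scalar in `[0, 1]`) and `axes`
#'   (an [OrdinationResult-class] of the fitted matrix, inertia fractions
#'   relative to the total inertia of M).
#' @examples
#' S <- rbind(c(-1, 1), c(1, -1))
#' rdaConstrained(S, c(0, 1))$constrainedFraction  # 1
#' @export
rdaConstrained <- function(M, x) {
    M <- if (methods::is(M, "CenteredLogMatrix")) M@S else as.matrix(M)
    Mc <- sweep(M, 2, colMeans(M))
    tot <- sum(Mc^2)
    if (tot == 0) stop("response matrix has zero variance")
    xc <- .designMatrix(x, nrow(Mc))
    qx <- qr(xc)
    fit <- qr.fitted(qx, Mc)
    frac <- sum(fit^2) / tot
    dec <- svd(fit, nu = qx$rank, nv = qx$rank)
    K <- max(1L, qx$rank)
    ax <- methods::new("OrdinationResult",
        U = dec$u[, seq_len(K), drop = FALSE],
        V = dec$v[, seq_len(K), drop = FALSE],
        d = dec$d[seq_len(K)],
        explainedFraction = dec$d[seq_len(K)]^2 / tot,
        totalInertia = tot, K = K)
    list(constrainedFraction = frac, axes = ax)
}

## chi-square standardized residual matrix of a count table and its row
## weights; the workhorse of correspondence analysis
.caResiduals <- function(Y) {
    m <- .smat(Y)
    if (any(m < 0)) stop("counts must be nonnegative")
    tot <- sum(m)
    if (tot == 0) stop("empty table")
    P <- m / tot
    rw <- rowSums(P); cw <- colSums(P)
    if (any(rw == 0)) stop("zero row sum")
    if (any(cw == 0)) stop("zero column sum")
    E <- outer(rw, cw)
    list(Q = (P - E) / sqrt(E), rw = rw, cw = cw)
}

#' Canonical correspondence analysis: constrained-inertia fraction and axes
#'
#' Standard CCA: the chi-square standardized residual matrix of the count
#' table is projected, with row weights equal to the relative library
#' sizes, onto the weighted-centred explanatory design; the constrained
#' fraction is constrained inertia over total inertia.
#'
#' @param Y a [CountMatrix-class] or nonnegative samples-by-taxa matrix
#'   with positive row and column sums. May be transformed counts (e.g.
#'   square-rooted).
#' @param x explanatory variable, as in [rdaConstrained()]; must not be
#'   constant.
#' @return list with `constrainedFraction` and `axes` (SVD of the fitted
#'   residual matrix, inertia fractions relative to total inertia).
#' @export
ccaConstrained <- function(Y, x) {
    ca <- .caResiduals(Y)
    tot <- sum(ca$Q^2)
    if (tot == 0) stop("table has zero inertia")
    x <- if (is.factor(x) || is.character(x))
        stats::model.matrix(~ factor(x))[, -1, drop = FALSE] else as.matrix(x)
    if (nrow(x) != nrow(ca$Q))
        stop("explanatory variable length does not match rows")
    ## weighted centring, then scale rows by sqrt(rw) so ordinary least
    ## squares on the scaled design is weighted least squares on x
    xc <- sweep(x, 2, colSums(x * ca$rw))
    if (all(abs(xc) < 1e-12)) stop("constant explanatory variable")
    xw <- xc * sqrt(ca$rw)
    qx <- qr(xw)
    fit <- qr.fitted(qx, ca$Q)
    frac <- sum(fit^2) / tot
    dec <- svd(fit, nu = qx$rank, nv = qx$rank)
    K <- max(1L, qx$rank)
    ax <- methods::new("OrdinationResult",
        U = dec$u[, seq_len(K), drop = FALSE],
        V = dec$v[, seq_len(K), drop = FALSE],
        d = dec$d[seq_len(K)],
        explainedFraction = dec$d[seq_len(K)]^2 / tot,
        totalInertia = tot, K = K)
    list(constrainedFraction = frac, axes = ax)
}

#' Monte Carlo permutation test on the constrained-inertia fraction
#'
#' Tests the association between a count (or transformed) matrix and an
#' explanatory variable by free permutation of the rows of `x`. The test
#' statistic is the constrained-inertia fraction of [rdaConstrained()] or
#' [ccaConstrained()]; the p-value follows the add-one convention
#' `(1 + #(perm >= observed)) / (nPerm + 1)` with ties counted as
#' greater-or-equal. For a single numeric explanatory vector the RDA
#' statistic is computed for all permutations in one matrix product.
#'
#' @param M response: a [CenteredLogMatrix-class] or numeric matrix for
#'   `method = "rda"`; a [CountMatrix-class] or nonnegative matrix for
#'   `method = "cca"`.
#' @param x explanatory variable (vector, factor or design matrix).
#' @param nPerm number of permutations (default 999).
#' @param method `"rda"` (least-squares projection of a centred matrix) or
#'   `"cca"` (chi-square residual projection with row weights).
#' @return an [RdaTestResult-class].
#' @examples
#' set.seed(1)
#' M <- matrix(rnorm(60), nrow = 10)
#' permutationTest(M, rep(0:1, each = 5), nPerm = 99)
#' @export
permutationTest <- function(M, x, nPerm = 999L, method = c("rda", "cca")) {
    method <- match.arg(method)
    nPerm <- as.integer(nPerm)
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (method == "rda") {
        Mm <- if (methods::is(M, "CenteredLogMatrix")) M@S else as.matrix(M)
        Mc <- sweep(Mm, 2, colMeans(Mm))
        tot <- sum(Mc^2)
        if (tot == 0) stop("response matrix has zero variance")
        if (is.numeric(x) && is.null(dim(x))) {
            ## fast path: statistic for every permutation in one product
            xc <- x - mean(x)
            cn <- sum(xc^2)
            if (cn == 0) stop("constant explanatory variable")
            obs <- sum(crossprod(xc, Mc)^2) / (cn * tot)
            P <- matrix(0, nPerm, length(xc))
            for (k in seq_len(nPerm)) P[k, ] <- xc[sample.int(length(xc))]
            perm <- rowSums((P %*% Mc)^2) / (cn * tot)
        } else {
            obs <- rdaConstrained(Mc, x)$constrainedFraction
            perm <- vapply(seq_len(nPerm), function(k) {
                idx <- sample.int(nrow(Mc))
                xs <- if (is.null(dim(x))) x[idx] else x[idx, , drop = FALSE]
                rdaConstrained(Mc, xs)$constrainedFraction
            }, numeric(1))
        }
    } else {
        ca <- .caResiduals(M)
        tot <- sum(ca$Q^2)
        if (tot == 0) stop("table has zero inertia")
        statCCA <- function(xv) {
            xc <- xv - sum(xv * ca$rw)
            if (all(abs(xc) < 1e-12)) stop("constant explanatory variable")
            xw <- xc * sqrt(ca$rw)
            sum(crossprod(xw, ca$Q)^2) / (sum(xw^2) * tot)
        }
        if (!(is.numeric(x) && is.null(dim(x))))
            stop("method = 'cca' supports a single explanatory vector")
        obs <- statCCA(x)
        perm <- vapply(seq_len(nPerm), function(k)
            statCCA(x[sample.int(length(x))]), numeric(1))
    }
    p <- (1 + sum(perm >= obs)) / (nPerm + 1)
    methods::new("RdaTestResult", statistic = obs, permStats = perm,
                 nPerm = nPerm, pValue = p, method = method)
}

#' @describeIn RdaTestResult the permutation p-value.
#' @export
setMethod("pValue", "RdaTestResult", function(x) x@pValue)

#' @describeIn RdaTestResult the observed constrained-inertia fraction.
#' @export
setMethod("constrainedFraction", "RdaTestResult", function(x) x@statistic)

#' @describeIn RdaTestResult the permutation distribution of the statistic.
#' @export
setMethod("permStats", "RdaTestResult", function(x) x@permStats)

setMethod("show", "RdaTestResult", function(object) {
    cat(sprintf(
        "%s permutation test: constrained fraction %.4f, p = %.4g (%d permutations)\n",
        toupper(object@method), object@statistic, object@pValue,
        object@nPerm))
})
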