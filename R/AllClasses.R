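#' Sample-by-taxon count table
#'
#' An integer count table of taxa observed in samples, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with taxa as rows and samples
#' as columns (Bioconductor convention) and a single assay named `"counts"`.
#' Ordination functions in this package work on the samples-by-taxa
#' orientation; use [countMatrix()] to obtain it.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`.
#' @seealso [CountMatrix()] for construction, [librarySizes()],
#'   [taxonPrevalence()], [prevalenceFilter()], [zeroFraction()].
#' @export
setClass("CountMatrix", contains = "SummarizedExperiment")

.validCountMatrix <- function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(m))
            msg <- c(msg, "counts must be numeric")
        else {
            if (any(!is.finite(m)))
                msg <- c(msg, "counts must be finite")
            else {
                if (any(m < 0))
                    msg <- c(msg, "counts must be nonnegative")
                if (max(abs(m - round(m))) > 1e-8)
                    msg <- c(msg, "counts must be integer-valued")
            }
        }
        if (is.null(rownames(object)) || is.null(colnames(object)))
            msg <- c(msg, "taxon and sample identifiers are required")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("CountMatrix", .validCountMatrix)

#' Double-centred log count matrix
#'
#' Holds the double-centred matrix S of a pseudo-counted log count table L:
#' `S[i,j] = L[i,j] - r[i] - c[j] + grandMean`, where `r` are the row means
#' of L (samples), `c` the column means (taxa) and `grandMean` the global
#' mean. Every row and every column of S sums to zero, and
#' `S + outer(r, c, "+") - grandMean` reconstructs L exactly. The row means
#' r are the quantity that leaks into clr-transformed sparse data.
#'
#' @slot S numeric matrix, samples x taxa, double-centred.
#' @slot r numeric vector of row means of L (one per sample).
#' @slot c numeric vector of column means of L (one per taxon).
#' @slot grandMean numeric scalar, global mean of L.
#' @slot pseudoCount numeric scalar, pseudo-count used to form L.
#' @seealso [doubleCenter()], [logRatioMatrix()], [lrPCA()],
#'   [correlationDiagnostic()].
#' @export
setClass("CenteredLogMatrix",
    representation(S = "matrix", r = "numeric", c = "numeric",
                   grandMean = "numeric", pseudoCount = "numeric"))

.validCenteredLogMatrix <- function(object) {
    msg <- NULL
    S <- object@S
    if (nrow(S) != length(object@r))
        msg <- c(msg, "length(r) must equal nrow(S)")
    if (ncol(S) != length(object@c))
        msg <- c(msg, "length(c) must equal ncol(S)")
    if (length(object@grandMean) != 1L)
        msg <- c(msg, "grandMean must be a scalar")
    if (nrow(S) > 0 && ncol(S) > 0) {
        if (max(abs(rowSums(S))) > 1e-10 * ncol(S))
            msg <- c(msg, "rows of S must sum to zero")
        if (max(abs(colSums(S))) > 1e-10 * nrow(S))
            msg <- c(msg, "columns of S must sum to zero")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("CenteredLogMatrix", .validCenteredLogMatrix)

#' Simulation parameters for the negative-binomial count model
#'
#' Parameters of the generative model
#' `log(mu[i,j]) = a[i] + t[j] + b[j] * x[i]`, with counts drawn from a
#' negative binomial with mean `mu` and size `dispersionSize` (size 1 gives
#' variance `mu + mu^2`). `a` controls the library size
#' (`a ~ N(0, sigmaA^2)`), `t` the overall taxon abundance
#' (`t ~ N(0, sigmaT^2)`), and `nDA` randomly chosen taxa receive a
#' treatment effect of `+log(foldChange)` or `-log(foldChange)` with equal
#' probability. The binary treatment `x` is assigned by a logistic model in
#' `a` with coupling strength `gamma` (see [assignTreatment()]), so that
#' `gamma > 0` correlates treatment with library size.
#'
#' @slot I integer, number of samples (must be even).
#' @slot J integer, number of taxa.
#' @slot sigmaA nonnegative numeric, SD of the sample (library-size) effect.
#' @slot sigmaT nonnegative numeric, SD of the taxon abundance effect.
#' @slot foldChange numeric >= 1, multiplicative treatment effect.
#' @slot nDA integer in `[0, J]`, number of differentially abundant taxa.
#' @slot gamma nonnegative numeric, treatment--library-size coupling.
#' @slot dispersionSize positive numeric, negative-binomial size parameter.
#' @slot minPrevalence integer, taxa present in fewer samples are removed.
#' @slot seed integer or NA, optional RNG seed used by [simulateDataset()].
#' @seealso [SimParams()], [drawEffects()], [simulateDataset()].
#' @export
setClass("SimParams",
    representation(I = "integer", J = "integer", sigmaA = "numeric",
                   sigmaT = "numeric", foldChange = "numeric",
                   nDA = "integer", gamma = "numeric",
                   dispersionSize = "numeric", minPrevalence = "integer",
                   seed = "integer"))

.validSimParams <- function(object) {
    msg <- NULL
    if (object@I < 2L || object@I %% 2L != 0L)
        msg <- c(msg, "I must be even and >= 2 (balanced groups)")
    if (object@J < 1L)
        msg <- c(msg, "J must be >= 1")
    if (object@nDA < 0L || object@nDA > object@J)
        msg <- c(msg, "nDA must lie in [0, J]")
    if (object@sigmaA < 0 || object@sigmaT < 0 || object@gamma < 0)
        msg <- c(msg, "sigmaA, sigmaT and gamma must be >= 0")
    if (object@foldChange < 1)
        msg <- c(msg, "foldChange must be >= 1")
    if (object@dispersionSize <= 0)
        msg <- c(msg, "dispersionSize must be > 0")
    if (object@minPrevalence < 0L)
        msg <- c(msg, "minPrevalence must be >= 0")
    if (is.null(msg)) TRUE else msg
}
setValidity("SimParams", .validSimParams)

#' One realized draw of the simulation effects
#'
#' @slot a numeric vector of sample (library-size) effects, length I.
#' @slot t numeric vector of taxon abundance effects, length J.
#' @slot bVec numeric vector of per-taxon treatment effects in
#'   `{+b, -b, 0}` with `b = log(foldChange)`, length J.
#' @slot x binary (0/1) treatment vector, length I, balanced
#'   (`sum(x) == I/2`).
#' @slot g numeric scalar balancing the Bernoulli treatment probabilities
#'   `min(1, g * plogis(gamma * a))` so they sum to I/2.
#' @seealso [drawEffects()], [assignTreatment()], [simulateCounts()].
#' @export
setClass("SimDraw",
    representation(a = "numeric", t = "numeric", bVec = "numeric",
                   x = "numeric", g = "numeric"))

.validSimDraw <- function(object) {
    msg <- NULL
    I <- length(object@a)
    if (length(object@x) != I)
        msg <- c(msg, "length(x) must equal length(a)")
    if (length(object@bVec) != length(object@t))
        msg <- c(msg, "length(bVec) must equal length(t)")
    if (!all(object@x %in% c(0, 1)))
        msg <- c(msg, "x must be binary (0/1)")
    else if (I > 0 && sum(object@x) != I / 2)
        msg <- c(msg, "treatment groups must be balanced (sum(x) == I/2)")
    if (length(object@g) != 1L || object@g < 0)
        msg <- c(msg, "g must be a nonnegative scalar")
    if (is.null(msg)) TRUE else msg
}
setValidity("SimDraw", .validSimDraw)

#' Result of a (possibly truncated) singular value decomposition ordination
#'
#' For log-ratio PCA this is the SVD `S = U diag(d) t(V)` of the
#' double-centred matrix; `explainedFraction` gives `d_k^2 / sum(d^2)` per
#' retained axis, with the denominator taken over all singular values of the
#' decomposed matrix.
#'
#' @slot U numeric matrix of sample scores, samples x K, orthonormal columns.
#' @slot V numeric matrix of taxon loadings, taxa x K, orthonormal columns.
#' @slot d numeric vector of singular values, nonincreasing, length K.
#' @slot explainedFraction numeric vector, per-axis fraction of total
#'   inertia, length K.
#' @slot totalInertia numeric scalar, sum of squares of the decomposed
#'   matrix.
#' @slot K integer, number of retained axes.
#' @seealso [lrPCA()], [sampleScores()], [taxonLoadings()],
#'   [singularValues()], [explainedFraction()].
#' @export
setClass("OrdinationResult",
    representation(U = "matrix", V = "matrix", d = "numeric",
                   explainedFraction = "numeric", totalInertia = "numeric",
                   K = "integer"))

.validOrdinationResult <- function(object) {
    msg <- NULL
    K <- object@K
    if (ncol(object@U) != K || ncol(object@V) != K || length(object@d) != K)
        msg <- c(msg, "U, V and d must all have K columns/entries")
    if (K > 1 && any(diff(object@d) > 1e-8))
        msg <- c(msg, "singular values must be nonincreasing")
    if (any(object@d < -1e-12))
        msg <- c(msg, "singular values must be nonnegative")
    if (length(object@explainedFraction) != K)
        msg <- c(msg, "explainedFraction must have one entry per axis")
    if (sum(object@explainedFraction) > 1 + 1e-8)
        msg <- c(msg, "explainedFraction must sum to at most 1")
    if (is.null(msg)) TRUE else msg
}
setValidity("OrdinationResult", .validOrdinationResult)

#' Monte Carlo permutation test result for constrained ordination
#'
#' The test statistic is the constrained-inertia fraction (the proportion of
#' the total sum of squares of the response matrix explained by the
#' explanatory variable). The p-value uses the add-one convention
#' `p = (1 + #(permStats >= statistic)) / (nPerm + 1)`, counting ties as
#' greater-or-equal.
#'
#' @slot statistic numeric scalar in `[0, 1]`, observed constrained
#'   fraction.
#' @slot permStats numeric vector of permuted statistics, length `nPerm`.
#' @slot nPerm integer, number of Monte Carlo permutations.
#' @slot pValue numeric scalar in `(0, 1]`.
#' @slot method character, `"rda"` or `"cca"`.
#' @seealso [permutationTest()], [pValue()], [constrainedFraction()].
#' @export
setClass("RdaTestResult",
    representation(statistic = "numeric", permStats = "numeric",
                   nPerm = "integer", pValue = "numeric",
                   method = "character"))

.validRdaTestResult <- function(object) {
    msg <- NULL
    if (object@statistic < -1e-12 || object@statistic > 1 + 1e-12)
        msg <- c(msg, "statistic must lie in [0, 1]")
    if (length(object@permStats) != object@nPerm)
        msg <- c(msg, "permStats must have length nPerm")
    p <- (1 + sum(object@permStats >= object@statistic)) / (object@nPerm + 1)
    if (abs(object@pValue - p) > 1e-12)
        msg <- c(msg, "pValue must follow the add-one permutation convention")
    if (is.null(msg)) TRUE else msg
}
setValidity("RdaTestResult", .validRdaTestResult)
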