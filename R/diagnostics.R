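#' Per-taxon correlation of the centred log matrix with r
#'
#' The first library-size diagnostic: for each taxon j, the Pearson
#' correlation over samples between column j of the double-centred matrix S
#' and the per-sample log mean r, plotted against the log of the mean
#' abundance of the taxon. A taxon whose column consists mostly of
#' pseudo-counted zeroes has `S[, j] ~ -r + const`, so its correlation is
#' close to -1; an increasing trend of the correlation with abundance,
#' starting from strongly negative values, indicates that r (and hence the
#' library size) leaks into the analysis.
#'
#' @param S a [CenteredLogMatrix-class].
#' @param Y the [CountMatrix-class] the transform came from (supplies mean
#'   abundances and prevalences), aligned with `S`.
#' @return a [S4Vectors::DataFrame] with one row per taxon and columns
#'   `rho_Sr` (NA for constant columns, flagged), `log_mean_abundance`
#'   (natural log of the column mean of the counts), `prevalence`, and
#'   `flagged` (constant-column indicator).
#' @examples
#' Y <- simulateDataset(SimParams(seed = 1L))
#' head(correlationDiagnostic(logRatioMatrix(Y), Y))
#' @export
correlationDiagnostic <- function(S, Y) {
    stopifnot(methods::is(S, "CenteredLogMatrix"))
    m <- .smat(Y)
    if (ncol(m) != ncol(S@S) || nrow(m) != nrow(S@S))
        stop("S and Y dimensions do not match")
    r <- S@r
    if (stats::sd(r) == 0)
        stop("r is constant: correlation with r is undefined")
    sdcol <- apply(S@S, 2, stats::sd)
    rho <- rep(NA_real_, ncol(m))
    ok <- sdcol > 1e-10 * max(1, max(abs(S@S)))  # constant up to rounding
    rho[ok] <- as.numeric(stats::cor(S@S[, ok, drop = FALSE], r))
    DataFrame(rho_Sr = rho,
              log_mean_abundance = unname(log(colMeans(m))),
              prevalence = unname(colSums(m > 0)),
              flagged = !ok,
              row.names = colnames(m))
}

#' Per-taxon contribution to a principal axis
#'
#' The second library-size diagnostic: the contribution of taxon j to axis
#' k is the square of its loading `V[j, k]`, which sums to one over taxa
#' because the columns of V are unit norm. Plotted against log mean
#' abundance, near-equal elevated contributions among the low-abundance
#' taxa (a V-shaped pattern in extreme cases) indicate an axis that carries
#' the effect of r rather than biology.
#'
#' @param ord an [OrdinationResult-class] from [lrPCA()].
#' @param Y the matching [CountMatrix-class].
#' @param axis axis index (<= number of retained axes).
#' @return a [S4Vectors::DataFrame] with columns `contribution`,
#'   `log_mean_abundance` and `prevalence`, one row per taxon.
#' @export
contributionDiagnostic <- function(ord, Y, axis = 1L) {
    stopifnot(methods::is(ord, "OrdinationResult"))
    axis <- as.integer(axis)
    if (axis < 1L || axis > ord@K) stop("axis out of range")
    m <- .smat(Y)
    if (nrow(ord@V) != ncol(m))
        stop("ordination and count table dimensions do not match")
    DataFrame(contribution = unname(ord@V[, axis]^2),
              log_mean_abundance = unname(log(colMeans(m))),
              prevalence = unname(colSums(m > 0)),
              row.names = colnames(m))
}

#' Fraction of the variance of S explained by r
#'
#' Fits a log-ratio RDA with r (the per-sample mean of the log counts) as
#' the constraining variable and returns the constrained-inertia fraction.
#' There is no universal reference value for what is "high", but the
#' fraction increases with library-size variability and is useful for
#' matched comparisons.
#'
#' @param S a [CenteredLogMatrix-class] with non-constant r.
#' @return scalar in `[0, 1]`.
#' @export
varianceExplainedByR <- function(S) {
    stopifnot(methods::is(S, "CenteredLogMatrix"))
    if (stats::sd(S@r) == 0) stop("r is constant")
    rdaConstrained(S, S@r)$constrainedFraction
}

#' Decision rule for library-size dependence
#'
#' Operationalizes the visual rule "an increasing trend of rho_Sr with log
#' mean abundance, starting from a low value": the flag is raised when (i)
#' the Spearman rank correlation between `rho_Sr` and `log_mean_abundance`
#' is positive with one-sided p < 0.05, and (ii) the median `rho_Sr` of the
#' lowest-abundance tercile is below `rhoThreshold`.
#'
#' @param diag a diagnostics table from [correlationDiagnostic()] with at
#'   least 10 non-missing rho values.
#' @param rhoThreshold threshold for the low-abundance median (default
#'   -0.5).
#' @return list with `flag` (logical), `spearmanRho`, `spearmanP`,
#'   `medianRhoLowTercile` and `rhoThreshold`.
#' @examples
#' Y <- simulateDataset(SimParams(sigmaA = 1, foldChange = 3, seed = 1L))
#' d <- correlationDiagnostic(logRatioMatrix(Y), Y)
#' flagLibSizeDependence(d)$flag
#' @export
flagLibSizeDependence <- function(diag, rhoThreshold = -0.5) {
    ok <- !is.na(diag$rho_Sr)
    if (sum(ok) < 10L) stop("need at least 10 taxa with defined rho_Sr")
    rho <- diag$rho_Sr[ok]
    ab <- diag$log_mean_abundance[ok]
    ct <- suppressWarnings(
        stats::cor.test(rho, ab, method = "spearman",
                        alternative = "greater", exact = FALSE))
    low <- ab <= stats::quantile(ab, 1 / 3)
    medLow <- stats::median(rho[low])
    list(flag = unname(ct$estimate > 0 && ct$p.value < 0.05 &&
                       medLow < rhoThreshold),
         spearmanRho = unname(ct$estimate),
         spearmanP = ct$p.value,
         medianRhoLowTercile = medLow,
         rhoThreshold = rhoThreshold)
}
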