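#' @name experiments
#' @title Type-I-error and power scenario harness
#'
#' @description
#' [runScenario()] repeatedly simulates count tables under a
#' [SimParams-class] setting, analyses each with one of six methods, and
#' records the rejection rate of the permutation test at level `alpha`
#' together with the per-simulation Pearson correlation between the
#' treatment and r. [runGrid()] maps over a list of scenarios with
#' reproducible per-scenario sub-seeds.
#'
#' Methods:
#' \describe{
#'   \item{`lr_rda`}{log-ratio RDA: pseudo-counted log, double centring,
#'     RDA permutation test.}
#'   \item{`lr_rda_gbm_counts`}{GBM zero imputation on counts, log,
#'     double centring, RDA.}
#'   \item{`lr_rda_gbm_props`}{GBM imputation on proportions, log, double
#'     centring, RDA.}
#'   \item{`log_props_rda`}{log of pseudo-counted proportions, RDA (column
#'     centring inside the RDA).}
#'   \item{`cca_counts`}{CCA on the raw counts.}
#'   \item{`cca_sqrt`}{CCA on square-rooted counts.}
#' }
NULL

.scenarioMethods <- c("lr_rda", "lr_rda_gbm_counts", "lr_rda_gbm_props",
                      "log_props_rda", "cca_counts", "cca_sqrt")

## one p-value for one simulated table
.analysisPValue <- function(Y, x, method, nPerm) {
    switch(method,
        lr_rda = pValue(permutationTest(logRatioMatrix(Y), x, nPerm, "rda")),
        lr_rda_gbm_counts = pValue(permutationTest(
            doubleCenter(log(gbmImpute(Y, onProportions = FALSE))),
            x, nPerm, "rda")),
        lr_rda_gbm_props = pValue(permutationTest(
            doubleCenter(log(gbmImpute(Y, onProportions = TRUE))),
            x, nPerm, "rda")),
        log_props_rda = pValue(permutationTest(logProportions(Y), x, nPerm,
                                               "rda")),
        cca_counts = pValue(permutationTest(Y, x, nPerm, "cca")),
        cca_sqrt = pValue(permutationTest(sqrtTransform(Y), x, nPerm,
                                          "cca")),
        stop("unknown method: ", method))
}

#' Run one simulation scenario
#'
#' @param params a [SimParams-class] describing the generative setting.
#' @param method analysis method, one of
#'   `r paste0('\x60', paste(.scenarioMethods, collapse = '\x60, \x60'), '\x60')`.
#' @param nSims number of simulated datasets (default 500).
#' @param nPerm permutations per test (default 199).
#' @param alpha rejection level (default 0.05); rejection counts p-values
#'   strictly below `alpha`.
#' @param extraFilter optional list with elements `minPrevalence` and/or
#'   `minMeanAbundance`: an additional, more stringent filter applied after
#'   the standard prevalence filter (the practical mitigation for
#'   library-size-driven type-I inflation).
#' @param seed optional integer seed set before the simulation loop.
#' @return one-row `data.frame`: scenario descriptors, `rejectionRate`,
#'   its binomial `se`, `meanCorrXR` and `meanAbsCorrXR` (signed and
#'   absolute Pearson correlation between x and r, averaged over
#'   simulations), and `nFailed` (simulations whose analysis errored;
#'   these are excluded from the rate, never silently dropped).
#' @examples
#' runScenario(SimParams(I = 10L, J = 40L, sigmaT = 1, minPrevalence = 2L),
#'             nSims = 5, nPerm = 19, seed = 1L)
#' @export
runScenario <- function(params, method = "lr_rda", nSims = 500L,
                        nPerm = 199L, alpha = 0.05, extraFilter = NULL,
                        seed = NULL) {
    stopifnot(methods::is(params, "SimParams"))
    method <- match.arg(method, .scenarioMethods)
    nSims <- as.integer(nSims)
    if (nSims < 1L) stop("nSims must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (!is.null(seed)) set.seed(as.integer(seed))
    pvals <- rep(NA_real_, nSims)
    corXR <- rep(NA_real_, nSims)
    for (s in seq_len(nSims)) {
        draw <- drawEffects(params)
        Y <- simulateCounts(draw, params)
        if (params@minPrevalence > 0L)
            Y <- prevalenceFilter(Y, params@minPrevalence)
        r <- rowMeans(logPseudo(Y))
        corXR[s] <- stats::cor(draw@x, r)
        if (!is.null(extraFilter))
            Y <- tryCatch(prevalenceFilter(Y,
                    minPrevalence = extraFilter$minPrevalence %||% 0L,
                    minMeanAbundance = extraFilter$minMeanAbundance %||% 0),
                error = function(e) NULL)
        pvals[s] <- tryCatch(
            if (is.null(Y)) NA_real_
            else .analysisPValue(Y, draw@x, method, nPerm),
            error = function(e) NA_real_)
    }
    nFailed <- sum(is.na(pvals))
    nOK <- nSims - nFailed
    rate <- if (nOK > 0) mean(pvals < alpha, na.rm = TRUE) else NA_real_
    data.frame(method = method, I = params@I, J = params@J,
               sigmaA = params@sigmaA, sigmaT = params@sigmaT,
               foldChange = params@foldChange, gamma = params@gamma,
               nSims = nSims, nPerm = as.integer(nPerm), alpha = alpha,
               rejectionRate = rate,
               se = if (nOK > 0) sqrt(rate * (1 - rate) / nOK) else NA_real_,
               meanCorrXR = mean(corXR, na.rm = TRUE),
               meanAbsCorrXR = mean(abs(corXR), na.rm = TRUE),
               nFailed = nFailed,
               stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a grid of scenarios
#'
#' Each scenario is a list with any [SimParams()] arguments plus optional
#' `method`, `nSims`, `nPerm`, `alpha`, `extraFilter` and `seed`. Scenarios
#' without their own `seed` receive an independent sub-seed drawn from
#' `seed`, so the grid is reproducible as a whole while duplicated
#' scenarios with an explicit identical `seed` give identical rows.
#'
#' @param scenarios list of scenario lists (may be empty).
#' @param seed master seed for deriving per-scenario sub-seeds.
#' @return `data.frame` with one row per scenario (empty for an empty
#'   grid).
#' @examples
#' g <- list(list(sigmaA = 0, I = 10, J = 40, sigmaT = 1,
#'                minPrevalence = 2, nSims = 3, nPerm = 19))
#' runGrid(g, seed = 1)
#' @export
runGrid <- function(scenarios, seed = NULL) {
    if (length(scenarios) == 0) {
        out <- runScenario(SimParams(I = 2L, J = 1L, nDA = 0L,
                                     minPrevalence = 0L),
                           nSims = 1L, nPerm = 1L)
        return(out[0, ])
    }
    if (!is.null(seed)) set.seed(as.integer(seed))
    subSeeds <- sample.int(.Machine$integer.max - 1L, length(scenarios))
    rows <- lapply(seq_along(scenarios), function(i) {
        sc <- scenarios[[i]]
        pArgs <- sc[intersect(names(sc), names(formals(SimParams)))]
        params <- do.call(SimParams, pArgs)
        runScenario(params,
                    method = sc$method %||% "lr_rda",
                    nSims = sc$nSims %||% 500L,
                    nPerm = sc$nPerm %||% 199L,
                    alpha = sc$alpha %||% 0.05,
                    extraFilter = sc$extraFilter,
                    seed = sc$seed %||% subSeeds[i])
    })
    do.call(rbind, rows)
}

#' Average correlation between treatment and r across simulations
#'
#' For each simulated draw (no treatment effect, `foldChange = 1`), r is
#' computed as the row means of the pseudo-counted log table after the
#' prevalence filter and correlated with the treatment x; the signed and
#' absolute correlations are averaged over draws. With `gamma = 2` and
#' `sigmaA` of 0.25, 0.5 and 1 the mean correlation is about 0.23, 0.41
#' and 0.58.
#'
#' @param sigmaA library-size variability (SD of the sample effect).
#' @param gamma treatment--library-size coupling.
#' @param nSims number of simulated draws.
#' @param params base [SimParams-class]; `sigmaA`, `gamma` are overridden
#'   and `foldChange` forced to 1.
#' @param seed optional integer seed.
#' @return one-row `data.frame` with `meanCorrXR`, `meanAbsCorrXR`, `se`
#'   (Monte Carlo standard error of the signed mean) and `nSims`.
#' @examples
#' correlationXRSummary(0.25, 2, nSims = 20, seed = 1)
#' @export
correlationXRSummary <- function(sigmaA, gamma, nSims = 1000L,
                                 params = SimParams(), seed = NULL) {
    stopifnot(nSims >= 1L)
    if (!is.null(seed)) set.seed(as.integer(seed))
    params@sigmaA <- as.numeric(sigmaA)
    params@gamma <- as.numeric(gamma)
    params@foldChange <- 1
    methods::validObject(params)
    cs <- vapply(seq_len(nSims), function(s) {
        draw <- drawEffects(params)
        Y <- simulateCounts(draw, params)
        if (params@minPrevalence > 0L)
            Y <- prevalenceFilter(Y, params@minPrevalence)
        stats::cor(draw@x, rowMeans(logPseudo(Y)))
    }, numeric(1))
    data.frame(sigmaA = params@sigmaA, gamma = params@gamma,
               meanCorrXR = mean(cs), meanAbsCorrXR = mean(abs(cs)),
               se = stats::sd(cs) / sqrt(nSims), nSims = as.integer(nSims))
}
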