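#' Construct simulation parameters
#'
#' Defaults follow the reference simulation setting: 50 samples, 500 taxa,
#' `sigmaT = 2`, 100 differentially abundant taxa, negative-binomial size 1
#' (variance `mu + mu^2`), and removal of taxa present in fewer than 5
#' samples. `sigmaA` (library-size variability) defaults to 1, the level at
#' which library-size leakage dominates the first principal axis; study
#' levels of interest are 0, 0.25, 0.5 and 1.
#'
#' @param I even integer, number of samples.
#' @param J integer, number of taxa.
#' @param sigmaA nonnegative numeric, SD of the sample effect `a`.
#' @param sigmaT nonnegative numeric, SD of the taxon effect `t`.
#' @param foldChange numeric >= 1; the treatment multiplies the mean of a
#'   differentially abundant taxon by `foldChange` or `1/foldChange`.
#' @param nDA integer, number of differentially abundant taxa.
#' @param gamma nonnegative numeric, treatment--library-size coupling.
#' @param dispersionSize positive numeric, NB size parameter `k` giving
#'   variance `mu + mu^2 / k`.
#' @param minPrevalence integer, prevalence filter threshold.
#' @param seed optional integer seed used by [simulateDataset()].
#' @return a [SimParams-class] object.
#' @examples
#' SimParams(sigmaA = 0.5, foldChange = 1.5)
#' @export
SimParams <- function(I = 50L, J = 500L, sigmaA = 1, sigmaT = 2,
                      foldChange = 1, nDA = 100L, gamma = 0,
                      dispersionSize = 1, minPrevalence = 5L,
                      seed = NA_integer_) {
    methods::new("SimParams", I = as.integer(I), J = as.integer(J),
        sigmaA = as.numeric(sigmaA), sigmaT = as.numeric(sigmaT),
        foldChange = as.numeric(foldChange), nDA = as.integer(nDA),
        gamma = as.numeric(gamma), dispersionSize = as.numeric(dispersionSize),
        minPrevalence = as.integer(minPrevalence), seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
    cat(sprintf(paste0("SimParams: I=%d J=%d sigmaA=%g sigmaT=%g ",
                       "foldChange=%g nDA=%d gamma=%g size=%g minPrev=%d\n"),
        object@I, object@J, object@sigmaA, object@sigmaT, object@foldChange,
        object@nDA, object@gamma, object@dispersionSize,
        object@minPrevalence))
})

setMethod("show", "SimDraw", function(object) {
    cat(sprintf("SimDraw: %d samples (%d treated), %d taxa (%d DA), g=%.4f\n",
        length(object@a), sum(object@x), length(object@t),
        sum(object@bVec != 0), object@g))
})

#' Assign a balanced binary treatment coupled to the sample effect
#'
#' Each sample is assigned to the treatment group with probability
#' `min(1, g * plogis(gamma * a[i]))`. The balancing scalar `g` is found by
#' root bisection so that the probabilities sum to `I/2`, and the Bernoulli
#' draw is repeated until the groups are exactly balanced
#' (`sum(x) == I/2`), which preserves the Bernoulli mechanism conditionally
#' on balance. With `gamma = 0` every probability is 0.5 and `g = 1`.
#' Probabilities are clipped at 1 where `g * plogis(gamma * a) > 1`.
#'
#' @param a numeric vector of sample effects (even length).
#' @param gamma nonnegative coupling strength.
#' @param maxTries integer, cap on balance redraws.
#' @return list with components `x` (binary vector, `sum(x) == I/2`) and
#'   `g` (the balancing scalar).
#' @examples
#' set.seed(1)
#' assignTreatment(rnorm(10), gamma = 2)
#' @export
assignTreatment <- function(a, gamma, maxTries = 1e5L) {
    I <- length(a)
    if (I %% 2L != 0L) stop("length(a) must be even")
    if (gamma < 0) stop("gamma must be >= 0")
    s <- stats::plogis(gamma * a)
    if (gamma == 0) {
        g <- 1
    } else {
        f <- function(g) sum(pmin(1, g * s)) - I / 2
        g <- stats::uniroot(f, c(0, 1 / min(s)), tol = 1e-12)$root
    }
    p <- pmin(1, g * s)
    for (k in seq_len(maxTries)) {
        x <- stats::rbinom(I, 1L, p)
        if (sum(x) == I / 2) return(list(x = as.numeric(x), g = g))
    }
    stop(sprintf(
        "failed to reach balanced groups in %d draws (last sum(x) = %d, target %d)",
        maxTries, sum(x), I / 2L))
}

#' Draw the random effects of one simulation replicate
#'
#' Draws `a ~ N(0, sigmaA^2)`, `t ~ N(0, sigmaT^2)`, chooses `nDA` taxa
#' uniformly without replacement and assigns each `+log(foldChange)` or
#' `-log(foldChange)` with probability one half, then assigns the balanced
#' treatment via [assignTreatment()].
#'
#' @param params a [SimParams-class] object.
#' @return a [SimDraw-class] object.
#' @examples
#' set.seed(1)
#' drawEffects(SimParams(I = 10L, J = 20L, nDA = 4L, foldChange = 2))
#' @export
drawEffects <- function(params) {
    stopifnot(methods::is(params, "SimParams"))
    a <- stats::rnorm(params@I, 0, params@sigmaA)
    t <- stats::rnorm(params@J, 0, params@sigmaT)
    b <- log(params@foldChange)
    bVec <- numeric(params@J)
    if (b != 0 && params@nDA > 0L) {
        da <- sample.int(params@J, params@nDA)
        bVec[da] <- ifelse(stats::runif(params@nDA) < 0.5, b, -b)
    }
    at <- assignTreatment(a, params@gamma)
    methods::new("SimDraw", a = a, t = t, bVec = bVec, x = at$x, g = at$g)
}

#' Simulate a negative-binomial count table from a realized draw
#'
#' Cell `(i, j)` is drawn independently from a negative binomial with mean
#' `mu[i,j] = exp(a[i] + t[j] + bVec[j] * x[i])` and size
#' `dispersionSize` (size 1 gives variance `mu + mu^2`). No filtering is
#' applied here; see [prevalenceFilter()].
#'
#' @param draw a [SimDraw-class].
#' @param params the [SimParams-class] the draw came from (supplies
#'   `dispersionSize`).
#' @return a [CountMatrix-class] with `length(a)` samples and `length(t)`
#'   taxa.
#' @examples
#' set.seed(1)
#' p <- SimParams(I = 6L, J = 10L)
#' simulateCounts(drawEffects(p), p)
#' @export
simulateCounts <- function(draw, params) {
    stopifnot(methods::is(draw, "SimDraw"), methods::is(params, "SimParams"))
    eta <- outer(draw@a, draw@t, "+") + outer(draw@x, draw@bVec)
    mu <- exp(eta)
    if (any(!is.finite(mu))) {
        bad <- which(!is.finite(mu), arr.ind = TRUE)[1, ]
        stop(sprintf("mean overflow at cell (%d, %d): eta = %g",
                     bad[1], bad[2], eta[bad[1], bad[2]]))
    }
    I <- length(draw@a); J <- length(draw@t)
    y <- matrix(stats::rnbinom(I * J, size = params@dispersionSize, mu = mu),
                nrow = I, ncol = J)
    CountMatrix(y, samplesAsRows = TRUE)
}

#' Simulate one filtered dataset and keep the generative truth
#'
#' Convenience wrapper: draws effects, simulates counts, applies the
#' prevalence filter from `params`, and stores the [SimDraw-class] and the
#' parameters in `metadata()` of the result (`$draw`, `$params`). If
#' `params@seed` (or the `seed` argument) is set, the RNG is seeded first so
#' the dataset is reproducible.
#'
#' @param params a [SimParams-class].
#' @param seed optional integer overriding `params@seed`.
#' @return a filtered [CountMatrix-class] with metadata `draw` and `params`.
#' @examples
#' Y <- simulateDataset(SimParams(seed = 7L))
#' S4Vectors::metadata(Y)$draw
#' @export
simulateDataset <- function(params = SimParams(), seed = NULL) {
    if (is.null(seed) && !is.na(params@seed)) seed <- params@seed
    if (!is.null(seed)) set.seed(as.integer(seed))
    draw <- drawEffects(params)
    y <- simulateCounts(draw, params)
    if (params@minPrevalence > 0L)
        y <- prevalenceFilter(y, params@minPrevalence)
    metadata(y)$draw <- draw
    metadata(y)$params <- params
    y
}
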