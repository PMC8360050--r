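test_that("SimParams validates its invariants", {
    expect_error(SimParams(I = 7L), "even")
    expect_error(SimParams(nDA = 600L), "nDA")
    expect_error(SimParams(sigmaA = -1), ">= 0")
    expect_error(SimParams(foldChange = 0.5), "foldChange")
    expect_error(SimParams(dispersionSize = 0), "dispersionSize")
})

test_that("degenerate parameters give degenerate effects", {
    set.seed(1)
    d0 <- drawEffects(SimParams(sigmaA = 0))
    expect_identical(d0@a, rep(0, 50))
    d1 <- drawEffects(SimParams(foldChange = 1))
    expect_identical(d1@bVec, rep(0, 500))
})

test_that("taxon effects have the declared spread and DA structure", {
    set.seed(42)
    p <- SimParams(foldChange = 2)
    tv <- replicate(20, drawEffects(p)@t)   # 10^4 taxon effects
    mcse <- 2 / sqrt(2 * length(tv))
    expect_lt(abs(sd(tv) - 2), 3 * mcse)
    d <- drawEffects(p)
    expect_identical(sum(d@bVec != 0), 100L)
    expect_true(all(abs(d@bVec[d@bVec != 0]) == log(2)))
})

test_that("treatment assignment is balanced with the logistic coupling", {
    set.seed(7)
    a <- rnorm(50)
    at0 <- assignTreatment(a, gamma = 0)
    expect_identical(at0$g, 1)
    expect_identical(sum(at0$x), 25)
    for (gamma in c(0.5, 2, 5)) {
        at <- assignTreatment(a, gamma)
        expect_identical(sum(at$x), 25)
        p <- pmin(1, at$g * plogis(gamma * a))
        expect_lt(abs(sum(p) - 25), 1e-6)
        expect_true(all(p >= 0 & p <= 1))
    }
})

test_that("a dominant sample effect forces treatment membership", {
    set.seed(11)
    a <- c(10, rnorm(9))
    hits <- mean(replicate(500, assignTreatment(a, gamma = 5)$x[1]))
    expect_gt(hits, 0.95)
})

test_that("corr(x, a) increases stochastically in gamma", {
    set.seed(13)
    meanCor <- vapply(c(0, 1, 2), function(g) {
        mean(replicate(200, {
            a <- rnorm(50)
            cor(assignTreatment(a, g)$x, a)
        }))
    }, numeric(1))
    expect_lt(abs(meanCor[1]), 0.06)
    expect_true(all(diff(meanCor) > 0))
})

test_that("counts follow the negative-binomial moments of the draw", {
    set.seed(3)
    d <- manualDraw(a = c(0.5, -0.5), t = c(0, 1, 2), x = c(0, 1))
    p <- SimParams(I = 2L, J = 3L, nDA = 0L, dispersionSize = 1)
    mu <- exp(outer(d@a, d@t, "+"))
    reps <- replicate(4000, countMatrix(simulateCounts(d, p)))
    m <- apply(reps, c(1, 2), mean)
    v <- apply(reps, c(1, 2), var)
    muSE <- sqrt((mu + mu^2) / 4000)
    expect_true(all(abs(m - mu) < 4 * muSE))
    ## variance of the sample variance of an NB is heavy-tailed; compare on
    ## a generous relative scale
    expect_true(all(abs(v - (mu + mu^2)) / (mu + mu^2) < 0.35))
    ## geometric special case: size 1, mu 1 has P(0) = 1/2
    zf <- mean(replicate(2000, counts(simulateCounts(
        manualDraw(a = c(0, 0), t = c(0, 0), x = c(0, 1)), p)) == 0))
    expect_lt(abs(zf - 0.5), 0.04)
})

test_that("expected zero fraction is one half under sigmoid symmetry", {
    ## pre-filter, size 1, fold change 1: P(zero) = E[1/(1 + e^T)] = 1/2
    ## for symmetric T, for any sigmaA
    set.seed(5)
    for (sa in c(0, 1)) {
        p <- SimParams(sigmaA = sa, minPrevalence = 0L)
        zf <- replicate(10, zeroFraction(simulateCounts(drawEffects(p), p)))
        expect_lt(abs(mean(zf) - 0.5), 3 * sd(zf) / sqrt(10) + 0.005)
    }
})

test_that("mean overflow is reported with the offending cell", {
    d <- manualDraw(a = c(800, 0), t = c(0, 800), x = c(0, 1))
    expect_error(simulateCounts(d, SimParams(I = 2L, J = 2L, nDA = 0L)), "overflow")
})

test_that("prevalence filter retains exactly the prevalent taxa", {
    Y <- cm(c(1, 0), c(2, 0), c(3, 1))     # prevalences 3 and 1
    f <- prevalenceFilter(Y, 2)
    expect_identical(dim(counts(f)), c(1L, 3L))
    expect_identical(rownames(counts(f)), "taxon_1")
    expect_identical(unname(librarySizes(f)), c(1, 2, 3))
    ## identity at threshold 0, error when nothing survives
    expect_identical(counts(prevalenceFilter(Y, 0)), counts(Y))
    expect_error(prevalenceFilter(Y, 4), "all taxa removed")
})

test_that("zero fraction counts zero cells", {
    expect_identical(zeroFraction(cm(c(1, 2), c(3, 4))), 0)
    expect_identical(zeroFraction(matrix(0, 2, 2)), 1)
    expect_identical(zeroFraction(cm(c(0, 1), c(2, 0))), 0.5)
})

test_that("simulated datasets are reproducible from the seed", {
    y1 <- simulateDataset(SimParams(seed = 99L))
    y2 <- simulateDataset(SimParams(seed = 99L))
    expect_identical(counts(y1), counts(y2))
    expect_identical(sum(S4Vectors::metadata(y1)$draw@x), 25)
})
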