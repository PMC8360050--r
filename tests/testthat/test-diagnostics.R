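test_that("an all-zero taxon correlates exactly -1 with r", {
    set.seed(31)
    Y <- CountMatrix(cbind(matrix(rpois(40, 30), 8, 5), 0))
    d <- correlationDiagnostic(logRatioMatrix(Y), Y)
    expect_equal(d$rho_Sr[6], -1)
    expect_false(d$flagged[6])
    expect_equal(d$prevalence[6], 0)
})

test_that("a column proportional to centred r correlates +1", {
    r0 <- c(1, 2, 3, 5)
    w <- c(2, 1, 0.5)
    L <- outer(r0, w)              # S columns are centred r0 times (w - wbar)
    S <- doubleCenter(L)
    d <- correlationDiagnostic(S, CountMatrix(matrix(1, 4, 3)))
    expect_equal(abs(d$rho_Sr[!d$flagged]),
                 rep(1, sum(!d$flagged)))
    expect_equal(d$rho_Sr[1], 1)   # w[1] > mean(w): same sign as r
    ## every S column lies in the span of centred r: fraction 1
    expect_equal(varianceExplainedByR(S), 1)
})

test_that("constant r is rejected, constant columns are flagged not fatal", {
    Y <- CountMatrix(matrix(c(1, 2, 4, 8, 2, 4, 8, 16), 2, 4, byrow = TRUE))
    expect_error(correlationDiagnostic(
        doubleCenter(matrix(c(0, 1, -1, 0, 1, -1), 2, 3, byrow = TRUE)),
        CountMatrix(matrix(1, 2, 3))), "constant")
    set.seed(32)
    m <- matrix(rpois(24, 9), 4, 6)
    L0 <- log1p(m[, 1:5])
    ## appending the row means as a column makes that S column constant
    S <- doubleCenter(cbind(L0, rowMeans(L0)))
    d <- correlationDiagnostic(S, CountMatrix(cbind(m[, 1:5], 1)))
    expect_true(d$flagged[6])
    expect_true(is.na(d$rho_Sr[6]))
})

test_that("contributions are squared loadings and sum to one per axis", {
    ord <- lrPCA(rbind(c(-1, 1), c(1, -1)))
    d <- contributionDiagnostic(ord, cm(c(1, 3), c(3, 1)), 1)
    expect_equal(d$contribution, c(0.5, 0.5))
    set.seed(33)
    Y <- randomCounts(9, 14, seed = 33)
    ord2 <- lrPCA(logRatioMatrix(Y), K = 5)
    for (ax in 1:5) {
        d2 <- contributionDiagnostic(ord2, Y, ax)
        expect_equal(sum(d2$contribution), 1)
    }
    expect_error(contributionDiagnostic(ord2, Y, 6L), "axis")
})

test_that("library-size variability drives the leakage diagnostics", {
    ## matched draws: same t, b, x; only the sample effects differ
    base <- SimParams(sigmaA = 0, foldChange = 3)
    set.seed(34)
    d0 <- drawEffects(base)
    a1 <- rnorm(50, 0, 1)
    d1 <- new("SimDraw", a = a1, t = d0@t, bVec = d0@bVec, x = d0@x,
              g = d0@g)
    set.seed(35)
    Y0 <- prevalenceFilter(simulateCounts(d0, base), 5)
    set.seed(35)
    Y1 <- prevalenceFilter(simulateCounts(d1, base), 5)
    S0 <- logRatioMatrix(Y0); S1 <- logRatioMatrix(Y1)
    ## more library-size variability, more variance tied to r
    expect_gt(varianceExplainedByR(S1), varianceExplainedByR(S0))
    ## the decision rule separates the two regimes
    expect_false(flagLibSizeDependence(correlationDiagnostic(S0, Y0))$flag)
    expect_true(flagLibSizeDependence(correlationDiagnostic(S1, Y1))$flag)
})

test_that("sigmaA = 1 reproduces the documented diagnostic pattern", {
    Y <- simulateDataset(SimParams(sigmaA = 1, foldChange = 3, seed = 36L))
    S <- logRatioMatrix(Y)
    d <- correlationDiagnostic(S, Y)
    ## rare taxa strongly negative, abundant taxa reaching positive values
    terc <- cut(rank(d$log_mean_abundance, ties.method = "first"), 3,
                labels = FALSE)
    expect_lt(median(d$rho_Sr[terc == 1]), -0.5)
    expect_gt(max(d$rho_Sr[terc == 3]), 0.3)
    ## elevated, near-equal contributions among rare taxa on the r axis:
    ## the rare-taxon median beats the overall median contribution
    ord <- lrPCA(S)
    ctr <- contributionDiagnostic(ord, Y, 1)$contribution
    expect_gt(median(ctr[terc == 1]), median(ctr))
})

test_that("the decision rule needs enough taxa and respects the threshold", {
    d <- S4Vectors::DataFrame(rho_Sr = rep(0.01, 5),
                              log_mean_abundance = 1:5)
    expect_error(flagLibSizeDependence(d), "at least 10")
    set.seed(37)
    d2 <- S4Vectors::DataFrame(rho_Sr = rnorm(60, 0, 0.02),
                               log_mean_abundance = rnorm(60))
    expect_false(flagLibSizeDependence(d2)$flag)
})
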