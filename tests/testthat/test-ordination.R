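test_that("log-ratio PCA recovers the hand-computed SVD", {
    ord <- lrPCA(rbind(c(-1, 1), c(1, -1)))
    expect_equal(singularValues(ord), 2)
    expect_equal(explainedFraction(ord), 1)
    expect_equal(taxonLoadings(ord)[, 1]^2, c(taxon_1 = 0.5, taxon_2 = 0.5),
                 ignore_attr = TRUE)
    ## zero matrix decomposes to zero singular values
    expect_equal(singularValues(lrPCA(matrix(0, 3, 4), K = 2)),
                 c(0, 0))
})

test_that("PCA conserves Frobenius norm and orthonormality", {
    set.seed(21)
    S <- doubleCenter(matrix(rnorm(12 * 30), 12, 30))
    ord <- lrPCA(S)
    expect_equal(sum(singularValues(ord)^2), sum(centeredMatrix(S)^2))
    expect_equal(crossprod(sampleScores(ord)), diag(ord@K),
                 ignore_attr = TRUE)
    expect_equal(crossprod(taxonLoadings(ord)), diag(ord@K),
                 ignore_attr = TRUE)
    expect_equal(sum(explainedFraction(ord)), 1)
    ## full-rank reconstruction
    rec <- sampleScores(ord) %*% diag(singularValues(ord)) %*%
        t(taxonLoadings(ord))
    expect_lt(max(abs(rec - centeredMatrix(S))), 1e-8)
    expect_error(lrPCA(S, K = 31), "K must lie")
})

test_that("PCA on S equals PCA on column-centred clr up to sign", {
    set.seed(22)
    Y <- randomCounts(10, 18, lambda = 3, seed = 22)
    S <- logRatioMatrix(Y)
    C <- clr(Y)
    Cc <- sweep(C, 2, colMeans(C))
    expect_equal(centeredMatrix(S), Cc, ignore_attr = TRUE)
    expect_equal(singularValues(lrPCA(S, K = 4)), svd(Cc)$d[1:4])
})

test_that("RDA constrained fraction matches the brute-force oracle", {
    ## a perfectly separating contrast explains everything
    expect_equal(rdaConstrained(rbind(c(-1, 1), c(1, -1)),
                                c(0, 1))$constrainedFraction, 1)
    ## x orthogonal to every column is annihilated
    M <- cbind(c(1, -1, 1, -1), c(2, -2, 2, -2))
    expect_lt(rdaConstrained(M, c(1, 1, -1, -1))$constrainedFraction, 1e-20)
    ## 4x3 toy vs explicit group-mean decomposition
    set.seed(23)
    M <- matrix(rnorm(12), 4, 3)
    x <- c(0, 0, 1, 1)
    expect_equal(rdaConstrained(M, x)$constrainedFraction,
                 bruteForceBetweenFraction(M, x))
    ## and on a larger random case with unbalanced groups
    M2 <- matrix(rnorm(9 * 6), 9, 6)
    x2 <- c(0, 0, 0, 0, 1, 1, 1, 1, 1)
    expect_equal(rdaConstrained(M2, x2)$constrainedFraction,
                 bruteForceBetweenFraction(M2, x2))
    expect_error(rdaConstrained(M, rep(1, 4)), "constant")
})

test_that("RDA and CCA fractions agree with vegan on simulated data", {
    skip_if_not_installed("vegan")
    set.seed(24)
    Y <- simulateDataset(SimParams(I = 20L, J = 60L, sigmaA = 0.5,
                                   foldChange = 2, nDA = 20L,
                                   minPrevalence = 2L, seed = 24L))
    x <- S4Vectors::metadata(Y)$draw@x
    S <- centeredMatrix(logRatioMatrix(Y))
    vr <- vegan::rda(S ~ x)
    expect_equal(rdaConstrained(S, x)$constrainedFraction,
                 unname(vr$CCA$tot.chi / vr$tot.chi))
    m <- countMatrix(Y)
    vc <- vegan::cca(m ~ x)
    expect_equal(ccaConstrained(Y, x)$constrainedFraction,
                 unname(vc$CCA$tot.chi / vc$tot.chi))
    ## square-rooted counts are count-like input for CCA as well
    vs <- vegan::cca(sqrt(m) ~ x)
    expect_equal(ccaConstrained(sqrtTransform(Y), x)$constrainedFraction,
                 unname(vs$CCA$tot.chi / vs$tot.chi))
})

test_that("CCA degenerate designs behave by contract", {
    Y <- randomCounts(6, 8, seed = 25)
    expect_error(ccaConstrained(Y, rep(2, 6)), "constant")
    ## a saturated design reproduces the rows: fraction 1
    X <- diag(6)[, -1]
    expect_equal(ccaConstrained(Y, X)$constrainedFraction, 1)
    expect_error(ccaConstrained(cbind(c(1, 1), c(0, 0)), c(0, 1)),
                 "column sum")
})

test_that("monotonicity: adding design columns never lowers the fraction", {
    set.seed(26)
    M <- matrix(rnorm(10 * 7), 10, 7)
    x1 <- rnorm(10); x2 <- rnorm(10)
    f1 <- rdaConstrained(M, cbind(x1))$constrainedFraction
    f12 <- rdaConstrained(M, cbind(x1, x2))$constrainedFraction
    expect_gte(f12, f1 - 1e-12)
    expect_true(f1 >= 0 && f12 <= 1 + 1e-12)
})

test_that("permutation p-values follow the add-one convention", {
    set.seed(27)
    M <- matrix(rnorm(10 * 6), 10, 6)
    x <- rep(c(0, 1), 5)
    res <- permutationTest(M, x, nPerm = 99)
    expect_identical(pValue(res),
                     (1 + sum(permStats(res) >= constrainedFraction(res))) / 100)
    expect_true(all(permStats(res) >= 0 & permStats(res) <= 1))
    ## two exchangeable rows: every permutation gives the same statistic
    res2 <- permutationTest(rbind(c(-1, 1), c(1, -1)), c(0, 1), nPerm = 19)
    expect_identical(pValue(res2), 1)
    ## factor and design-matrix paths agree with the vector fast path
    set.seed(28)
    resV <- permutationTest(M, x, nPerm = 49)
    set.seed(28)
    resF <- permutationTest(M, factor(x, labels = c("ctl", "trt")),
                            nPerm = 49)
    expect_equal(constrainedFraction(resV), constrainedFraction(resF))
    expect_equal(permStats(resV), permStats(resF))
})

test_that("permutation p-values are uniform under an exchangeable null", {
    set.seed(29)
    ps <- replicate(400, {
        M <- matrix(rnorm(12 * 8), 12, 8)
        pValue(permutationTest(M, rep(c(0, 1), 6), nPerm = 39))
    })
    ## super-uniformity at several thresholds, within binomial noise
    for (al in c(0.1, 0.25, 0.5)) {
        expect_lt(mean(ps <= al), al + 3 * sqrt(al * (1 - al) / 400))
    }
    expect_gt(mean(ps), 0.5 - 3 * 0.29 / sqrt(400))
    ## p lives on the grid k / (nPerm + 1)
    expect_true(all(abs(ps * 40 - round(ps * 40)) < 1e-12))
})
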