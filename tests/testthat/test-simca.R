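test_that("PCA core matches a dense SVD oracle and is orthonormal", {
    set.seed(1)
    X <- matrix(rnorm(24), 6, 4)
    m <- fitSimca(X, nComponents = 2, snv = FALSE, scaling = "center")
    P <- m@loadings
    expect_equal(crossprod(P), diag(2), tolerance = 1e-12)
    sv <- svd(scale(X, scale = FALSE))
    for (j in 1:2) {
        ## equal up to column sign
        expect_equal(min(sum((P[, j] - sv$v[, j])^2),
                         sum((P[, j] + sv$v[, j])^2)), 0, tolerance = 1e-20)
    }
    ## explained variance non-increasing per component
    r2 <- diff(c(0, m@varianceTable$R2cum))
    expect_true(all(diff(r2) <= 1e-12))
})

test_that("exact low-rank data yields a degenerate s0 and OD errors", {
    set.seed(2)
    L <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(12), 2, 6)
    m <- fitSimca(L, nComponents = 2, snv = FALSE, scaling = "center")
    expect_equal(m@s0, 0)
    expect_identical(m@odRegime, "degenerate")
    expect_error(orthogonalDistance(m, L), "degenerate")
})

test_that("score distance matches the explicit Mahalanobis oracle", {
    set.seed(3)
    for (i in 1:5) {
        X <- matrix(rnorm(48), 8, 6)
        m <- fitSimca(X, nComponents = 3, snv = FALSE, scaling = "center")
        Xs <- applyScalingRecord(m@scalingRecord, X)
        scores <- Xs %*% m@loadings
        ## PCA scores are uncorrelated, so the diagonal quadratic form equals
        ## the full Mahalanobis distance in score space
        expect_equal(unname(scoreDistance(m, X)),
                     unname(mahalanobisOracle(scores, scores)),
                     tolerance = 1e-10)
    }
    ## the training mean maps to the model center: SD = 0
    X <- matrix(rnorm(60), 10, 6) + 3
    m <- fitSimca(X, nComponents = 2, snv = FALSE, scaling = "pareto")
    expect_equal(unname(scoreDistance(m, colMeans(X))), 0, tolerance = 1e-20)
    ## algebraic identity for the training rows
    expect_equal(mean(m@trainSD), m@nComponents * (m@N - 1) / m@N)
})

test_that("T2 critical limit follows the F quantile formula", {
    expect_equal(t2Critical(25, 2, 0.05), qf(0.95, 2, 23) * 2 * 24 / 23)
    ## alpha -> 1 drives the limit to 0
    expect_lt(t2Critical(25, 2, 0.999), 0.01)
    ## C = 1 reduces to the squared Student t limit
    expect_equal(t2Critical(30, 1, 0.05), qt(0.975, 29)^2)
    expect_error(t2Critical(3, 3))
})

test_that("orthogonal distance obeys the pooled-variance identities", {
    set.seed(4)
    X <- matrix(rnorm(4 * 5), 4, 5)
    m <- fitSimca(X, nComponents = 1, snv = FALSE, scaling = "center")
    ## brute-force residual oracle
    Xs <- applyScalingRecord(m@scalingRecord, X)
    E <- Xs - (Xs %*% m@loadings) %*% t(m@loadings)
    si <- sqrt(rowSums(E^2) / (5 - 1))
    expect_equal(unname(orthogonalDistance(m, X)), unname(si / m@s0),
                 tolerance = 1e-12)
    ## a row inside the model plane has OD 0
    inPlane <- colMeans(X) + 0.3 * (m@loadings[, 1] * m@scalingRecord$divisor)
    expect_equal(unname(orthogonalDistance(m, inPlane)), 0, tolerance = 1e-12)
    ## pooled identity: mean of nu-corrected training OD^2 is exactly 1
    Y <- matrix(rnorm(200), 20, 10)
    m2 <- fitSimca(Y, nComponents = 3, snv = FALSE)
    expect_equal(mean(m2@trainOD^2), 1, tolerance = 1e-12)
    expect_equal(m2@nu, sqrt(20 / (20 - 3 - 1)))
})

test_that("OD critical limit applies the large-K rule and its fallback", {
    lim <- odCritical(50, 4, 256)
    expect_equal(attr(lim, "df2"), sqrt(45 * 252))
    expect_identical(attr(lim, "regime"), "largeK")
    df2 <- sqrt(45 * 252)
    df1 <- (100 + sqrt(256 - df2) - 4) * 50 / 45
    expect_equal(as.numeric(lim), sqrt(qf(0.95, df1, df2)))
    ## outside K > df2 > 100: uncorrected residual df
    lim2 <- odCritical(200, 7, 32)
    expect_identical(attr(lim2, "regime"), "fallback")
    expect_equal(attr(lim2, "df1"), (32 - 7) * 200 / 192)
    ## smaller alpha -> strictly larger limit
    expect_gt(odCritical(200, 7, 32, alpha = 0.01), odCritical(200, 7, 32, 0.05))
    expect_error(odCritical(5, 4, 4))
})

test_that("size selection recovers exact rank, shrinks on noise, is seeded", {
    set.seed(5)
    L <- matrix(rnorm(120), 60, 2) %*% matrix(rnorm(2 * 16), 2, 16) + 5
    selL <- selectSimcaSize(L, snv = FALSE, seed = 1)
    expect_identical(selL$nComponents, 2L)
    N <- matrix(rnorm(200 * 24), 200, 24)
    selN <- selectSimcaSize(N, snv = FALSE, seed = 1)
    expect_lte(selN$nComponents, 3L)
    expect_identical(selectSimcaSize(N, snv = FALSE, seed = 7),
                     selectSimcaSize(N, snv = FALSE, seed = 7))
})

test_that("projection flags against both limits and is consistent for training rows", {
    d <- authenticDesign(30L, 5L, seed = 6L)
    ss <- generateSpectra(d, builtinDevices()$A, artifacts = FALSE)
    m <- fitSimca(ss, seed = 6)
    pr <- project(m, ss, working = TRUE)
    expect_identical(unname(pr$verdict == "authentic"),
                     unname(pr$insideSD & pr$insideOD))
    ## fitted distances equal projection of the training set
    expect_equal(unname(pr$SD), m@trainSD, tolerance = 1e-10)
    expect_equal(unname(pr$OD), m@trainOD, tolerance = 1e-10)
    ## most training rows lie inside the joint region at alpha = 0.05 + 0.05
    expect_lt(mean(pr$verdict == "outlying"), 0.2)
    expect_error(project(m, matrix(0, 2, 10)), "mismatch")
})

test_that("wet-blended ammonium sulfate shifts the score distance with dose", {
    d <- SampleDesign(nCowSmp = 20L, nBuffaloMix = 0L,
                      adulterants = "ammonium_sulfate",
                      fraudLevels = c(0.5, 5, 10), nSpikedSmps = 5L,
                      blendingModes = "wet", nReplicates = 4L, seed = 8L)
    ss <- generateSpectra(d, builtinDevices()$D, artifacts = FALSE)
    m <- spectraMeta(ss)
    train <- ss[, m$adulterant == "none"]
    mod <- fitSimca(train, seed = 8)
    pr <- project(mod, ss)
    msd <- tapply(pr$SD, m$fraud_level_pct, mean)
    ## the indirect matrix response: mean SD climbs over the resolvable
    ## fraud levels and the top level stands far above the controls (at
    ## 0.5 % the dose shift is below the natural sample spread)
    expect_true(all(diff(msd[c("0.5", "5", "10")]) > 0))
    expect_gt(msd[["10"]], 3 * msd[["0"]])
})

test_that("a persisted model projects identically after restore", {
    d <- authenticDesign(15L, 4L, seed = 12L)
    ss <- generateSpectra(d, builtinDevices()$F, artifacts = FALSE)
    m <- fitSimca(ss, seed = 12)
    pre <- file.path(tempdir(), "simca")
    writeSimcaModel(m, pre)
    m2 <- readSimcaModel(pre)
    pr1 <- project(m, ss); pr2 <- project(m2, ss)
    expect_equal(pr1$SD, pr2$SD, tolerance = 1e-12)
    expect_equal(pr1$OD, pr2$OD, tolerance = 1e-12)
    expect_identical(pr1$verdict, pr2$verdict)
    expect_equal(m2@ODcrit, m@ODcrit)
    unlink(paste0(pre, c("_model.json", "_loadings.csv")))
})
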