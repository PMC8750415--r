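test_that("RMSE operators use the stated denominators", {
    expect_equal(rmseCalibration(c(1, 2, 3, 4), c(2, 1, 4, 3)), sqrt(4 / 2))
    expect_equal(rmseCalibration(1:5, 1:5), 0)
    ## homogeneity: doubling residuals doubles RMSEc
    y <- rnorm(10); r <- rnorm(10)
    expect_equal(rmseCalibration(y, y + 2 * r), 2 * rmseCalibration(y, y + r))
    expect_error(rmseCalibration(1:2, 1:2), "N > 2")
    expect_equal(rmseCrossValidation(c(3, 4), c(0, 0)), sqrt(25 / 2))
    expect_equal(rmseCrossValidation(1:4, 1:4), 0)
    expect_error(rmseCrossValidation(numeric(0), numeric(0)), "empty")
    ## same residual vector: CV denominator N beats calibration N - 2
    yp <- y + r
    expect_lt(rmseCrossValidation(y, yp), rmseCalibration(y, yp))
})

test_that("OPLS with zero orthogonal components is exactly 1-component PLS1", {
    set.seed(11)
    for (i in 1:5) {
        X <- matrix(rnorm(30 * 12), 30, 12)
        y <- rnorm(30)
        fit <- fitOpls(X, y, nOrtho = 0L)
        expect_equal(unname(fit@fitted), pls1Oracle(X, y), tolerance = 1e-8)
        Xnew <- matrix(rnorm(5 * 12), 5, 12)
        expect_equal(unname(predict(fit, Xnew)), pls1Oracle(X, y, Xnew),
                     tolerance = 1e-8)
    }
})

test_that("one orthogonal component absorbs y-orthogonal structured variation", {
    set.seed(12)
    for (i in 1:5) {
        n <- 24; K <- 10
        ## bilinear data: one predictive latent t1, one added latent t0 whose
        ## scores are orthogonal to both the centered response and t1
        t1 <- rnorm(n)
        y <- 2 * t1 + rnorm(n, 0, 0.3)
        t0 <- residuals(lm(rnorm(n) ~ y + t1))
        p1 <- rnorm(K); p0 <- rnorm(K)
        X0 <- t1 %o% p1
        Xa <- X0 + 5 * t0 %o% p0
        base <- fitOpls(X0, y, nOrtho = 0L)
        aug <- fitOpls(Xa, y, nOrtho = 1L)
        expect_equal(unname(aug@fitted), unname(base@fitted), tolerance = 1e-8)
        expect_identical(aug@nOrtho, 1L)
    }
})

test_that("a noise-free linear response is fitted exactly", {
    set.seed(13)
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- 3 * X[, 5] + 1
    ## once all response-orthogonal variation is filtered, the single
    ## predictive component reproduces an exact linear response
    fit <- fitOpls(X, y, nOrtho = 7L)
    expect_lt(fit@rmseC, 1e-8)
    expect_gt(fit@r2, 1 - 1e-12)
    expect_error(fitOpls(X, rep(1, 20)), "constant")
    expect_error(fitOpls(X, y, nOrtho = 50L), "rank")
})

test_that("venetian CV removes each sample once and is deterministic", {
    set.seed(14)
    X <- matrix(rnorm(40 * 9), 40, 9)
    groups <- rep(sprintf("S%02d", 1:10), each = 4)
    y <- rep(c(0, 1, 2, 3), times = 10) + rnorm(40, 0, 0.1)
    cv <- venetianCv(X, y, groups, nOrtho = 1L)
    expect_length(cv, 40L)
    ## out-of-fold prediction equals a manual refit without that sample
    g <- "S03"
    fit <- fitOpls(X[groups != g, ], y[groups != g], nOrtho = 1L)
    expect_equal(cv[groups == g],
                 unname(predict(fit, X[groups == g, , drop = FALSE])))
    expect_identical(cv, venetianCv(X, y, groups, nOrtho = 1L))
    expect_error(venetianCv(X, y, rep("a", 40)), "2 groups")
    ## redundancy limit: duplicated rows across groups make CV ~ calibration
    Xd <- rbind(X[1:4, ], X[1:4, ]); yd <- c(y[1:4], y[1:4])
    gd <- rep(c("a", "b"), each = 4)
    cvd <- venetianCv(Xd, yd, gd, nOrtho = 0L)
    cal <- fitOpls(Xd, yd, nOrtho = 0L)@fitted
    expect_equal(cvd, unname(cal), tolerance = 1e-8)
})

test_that("size selection is parsimonious and flags an unmet criterion", {
    set.seed(15)
    ## single-factor linear data: a small model suffices
    n <- 40; K <- 15
    t <- rnorm(n)
    X <- t %o% rnorm(K) + matrix(rnorm(n * K, 0, 0.05), n, K)
    y <- 2 * t + rnorm(n, 0, 0.05)
    groups <- rep(sprintf("S%d", 1:10), each = 4)
    sel <- selectOplsSize(X, y, groups, maxComponents = 6L)
    expect_lte(sel$nComponents, 3L)
    expect_true(sel$criterionMet)
    expect_identical(nrow(sel$curves), 6L)
    ## flat RMSEcv curve: smallest size chosen
    expect_identical(sel$curves$nComponents[1L], 1L)
    ## structureless response: fallback to the argmin with a flag
    yN <- rnorm(n)
    selN <- selectOplsSize(matrix(rnorm(n * K), n, K), yN, groups,
                           maxComponents = 4L)
    if (!selN$criterionMet)
        expect_identical(selN$nComponents,
                         selN$curves$nComponents[which.min(selN$curves$RMSEcv)])
})

test_that("dose recovery on synthetic spectra stays near the noise floor", {
    ## known dose-response on generated wet-blend spectra: predictions
    ## recover concentrations with RMSEcv within 3x the replicate noise
    d <- SampleDesign(nCowSmp = 10L, nBuffaloMix = 0L,
                      adulterants = "ammonium_sulfate",
                      fraudLevels = c(0.5, 5, 10), nSpikedSmps = 10L,
                      blendingModes = "wet", nReplicates = 10L, seed = 21L)
    ss <- generateSpectra(d, builtinDevices()$E, artifacts = FALSE)
    m <- spectraMeta(ss)
    M <- spectraMatrix(ss)
    key <- paste(m$smp_id, m$dose_g_per_100g)
    ord <- sort(unique(key))
    X <- rowsum(M, key)[ord, ] / as.vector(table(key)[ord])
    mdU <- m[!duplicated(key), ][match(ord, key[!duplicated(key)]), ]
    y <- mdU$dose_g_per_100g
    Xp <- snv(X)
    sel <- selectOplsSize(Xp, y, mdU$smp_id, maxComponents = 8L)
    cv <- venetianCv(Xp, y, mdU$smp_id, nOrtho = sel$nOrtho)
    ## irreducible error from the natural latent variability along the
    ## dose-response direction (moisture/particle/crystallinity channels)
    sigmaFloor <- 1 / sqrt((1.5 / 0.7)^2 + (0.2 / 0.12)^2 + (0.8 / 1)^2)
    expect_lt(rmseCrossValidation(y, cv), 3 * sigmaFloor)
})
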