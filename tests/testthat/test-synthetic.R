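test_that("component library is deterministic, pointwise and non-negative", {
    grid <- seq(740, 2500, by = 4)
    lib1 <- buildComponentLibrary(grid, seed = 7)
    lib2 <- buildComponentLibrary(grid, seed = 7)
    expect_identical(lib1, lib2)
    libOther <- buildComponentLibrary(grid, seed = 8)
    expect_false(identical(lib1, libOther))
    ## restriction to a sub-window equals pointwise restriction
    sub <- grid[grid >= 900 & grid <= 1700]
    libSub <- buildComponentLibrary(sub, seed = 7)
    for (nm in names(lib1))
        expect_equal(libSub[[nm]], lib1[[nm]][grid >= 900 & grid <= 1700])
    expect_true(all(vapply(lib1, function(v) all(v >= 0), logical(1))))
    expect_error(buildComponentLibrary(numeric(0)), "empty")
    expect_error(buildComponentLibrary(c(2, 1)), "increasing")
})

test_that("dose arithmetic follows the nitrogen / lactose bases", {
    ## (NH4)2SO4 nitrogen mass fraction from atomic masses
    expect_equal(nitrogenMassFraction("ammonium_sulfate"), 2 * 14.007 / 132.14)
    expect_equal(nitrogenMassFraction("ammonium_sulfate"), 0.2120, tolerance = 1e-3)
    ## zero fraud -> zero dose, any adulterant
    for (ad in c("ammonium_sulfate", "semicarbazide", "cornstarch"))
        expect_identical(doseForFraudLevel(ad, 0), 0)
    ## 5 % N-fraud at total N 5.28 g/100 g
    expect_equal(doseForFraudLevel("ammonium_sulfate", 5), 0.05 * 5.28 / 0.21202,
                 tolerance = 1e-4)
    expect_equal(doseForFraudLevel("ammonium_sulfate", 5), 1.245, tolerance = 1e-3)
    ## cornstarch on the lactose basis with the 0.9 equivalence factor
    expect_equal(doseForFraudLevel("cornstarch", 9), 0.09 * 52 / 0.9)
    expect_error(doseForFraudLevel("ammonium_sulfate", -1))
    expect_error(doseForFraudLevel("sand", 1))
    ## inverse pair, both bases
    for (ad in c("ammonium_sulfate", "semicarbazide", "cornstarch"))
        for (f in c(0.5, 5, 10))
            expect_equal(fraudPctConversion(doseForFraudLevel(ad, f), ad), f)
    ## the composition default ties 0.82 g/100 g to 3.29 % N-fraud
    expect_equal(fraudPctConversion(0.82, "ammonium_sulfate"), 3.29,
                 tolerance = 5e-3)
})

test_that("design arithmetic reproduces the study counts", {
    d <- SampleDesign()
    expect_identical(samplesPerMode(d), 163L)
    ds <- designSummary(d, builtinDevices())
    expect_identical(ds$totalSpectra, 26080L)
    expect_identical(ds$oplsRowsPerFit, 40L)
    expect_identical(ds$nOplsModels, 48L)
    expect_equal(wetBlendTotalSolids(30, 45), 40)
    ## row count = samples x replicates over randomized small designs
    set.seed(1)
    for (i in 1:5) {
        d <- SampleDesign(nCowSmp = sample(4:10, 1), nBuffaloMix = sample(0:2, 1),
                          adulterants = sample(c("ammonium_sulfate", "cornstarch"),
                                               sample(1:2, 1)),
                          fraudLevels = c(1, 5), nSpikedSmps = 3L,
                          blendingModes = sample(list("dry", c("dry", "wet")), 1)[[1]],
                          nReplicates = sample(2:4, 1), seed = i)
        ss <- generateSpectra(d, builtinDevices()$A, artifacts = FALSE)
        expect_identical(nSpectra(ss),
                         samplesPerMode(d) * length(d@blendingModes) * d@nReplicates)
    }
})

test_that("generation is seed-deterministic and seeds differ", {
    d <- authenticDesign(6L, 3L, seed = 42L)
    s1 <- generateSpectra(d, builtinDevices()$B)
    s2 <- generateSpectra(d, builtinDevices()$B)
    expect_identical(spectraMatrix(s1), spectraMatrix(s2))
    expect_identical(spectraMeta(s1), spectraMeta(s2))
    d2 <- authenticDesign(6L, 3L, seed = 43L)
    s3 <- generateSpectra(d2, builtinDevices()$B)
    expect_false(identical(spectraMatrix(s1), spectraMatrix(s3)))
})

test_that("noise-free, scatter-free replicates are identical and dose response is monotone", {
    d <- SampleDesign(nCowSmp = 8L, nBuffaloMix = 0L,
                      adulterants = "ammonium_sulfate", fraudLevels = c(0.5, 5, 10),
                      nSpikedSmps = 4L, blendingModes = "dry",
                      nReplicates = 3L, seed = 3L)
    ss <- generateSpectra(d, builtinDevices()$D, scatter = FALSE, noise = FALSE,
                          artifacts = FALSE)
    X <- spectraMatrix(ss)
    m <- spectraMeta(ss)
    for (sid in unique(m$sample_id)) {
        rows <- X[m$sample_id == sid, , drop = FALSE]
        expect_equal(max(abs(sweep(rows, 2L, rows[1L, ]))), 0)
    }
    ## mean distance from the blank centroid is non-decreasing in fraud
    ## level; the blank population is the spiked parents' own controls so
    ## that natural composition differences cancel out
    parents <- unique(m$smp_id[m$adulterant != "none"])
    blank <- colMeans(X[m$adulterant == "none" & m$smp_id %in% parents, ,
                        drop = FALSE])
    dist <- vapply(c(0, 0.5, 5, 10), function(lev) {
        sel <- if (lev == 0) m$adulterant == "none" & m$smp_id %in% parents
               else m$fraud_level_pct == lev
        sqrt(sum((colMeans(X[sel, , drop = FALSE]) - blank)^2))
    }, numeric(1))
    expect_true(all(diff(dist) > 0))
})

test_that("sample compositions are consistent across devices", {
    d <- authenticDesign(5L, 2L, seed = 9L)
    sA <- generateSpectra(d, builtinDevices()$A, scatter = FALSE, noise = FALSE,
                          artifacts = FALSE)
    sB <- generateSpectra(d, builtinDevices()$B, scatter = FALSE, noise = FALSE,
                          artifacts = FALSE)
    ## same design seed: the same samples are measured on both devices, so
    ## sample-mean absorbance ranks in an overlapping region agree
    mA <- spectraMeta(sA); mB <- spectraMeta(sB)
    inA <- wavelengths(sA) >= 960 & wavelengths(sA) <= 980
    inB <- wavelengths(sB) >= 960 & wavelengths(sB) <= 980
    lvlA <- tapply(rowMeans(spectraMatrix(sA)[, inA]), mA$sample_id, mean)
    lvlB <- tapply(rowMeans(spectraMatrix(sB)[, inB]), mB$sample_id, mean)
    expect_gt(cor(lvlA, lvlB[names(lvlA)]), 0.99)
})

test_that("artifact injection flags exactly the modified rows", {
    d <- authenticDesign(10L, 4L, seed = 5L)
    base <- generateSpectra(d, builtinDevices()$G, artifacts = FALSE)
    dev <- DeviceProfile("G", 1550, 1950, nChannels = 80L, noiseSd = 0.0045,
                         artifactKinds = "step_random", artifactRate = 0.3)
    out <- injectArtifacts(base, dev, seed = 5L)
    changed <- rowSums(spectraMatrix(out) != spectraMatrix(base)) > 0
    expect_identical(unname(spectraMeta(out)$is_outlier_truth), unname(changed))
    expect_gt(sum(changed), 0)
    ## rate 0 is a no-op
    devOff <- DeviceProfile("G", 1550, 1950, nChannels = 80L, artifactRate = 0)
    same <- injectArtifacts(base, devOff, seed = 5L)
    expect_identical(spectraMatrix(same), spectraMatrix(base))
    expect_false(any(spectraMeta(same)$is_outlier_truth))
})

test_that("fringe artifacts are pure sinusoids and fixed steps share breakpoints", {
    flat <- flatSpectraSet(n = 12L, K = 64L)
    devF <- DeviceProfile("C", 900, 1700, nChannels = 64L,
                          artifactKinds = "fringe", artifactRate = 1)
    out <- injectArtifacts(flat, devF, seed = 2L)
    grid <- wavelengths(out)
    rssAt <- function(f, dif) {
        B <- cbind(sin(2 * pi * (grid - grid[1]) * f),
                   cos(2 * pi * (grid - grid[1]) * f))
        fit <- lm.fit(B, dif)
        list(rss = sum(fit$residuals^2),
             amp = sqrt(sum(fit$coefficients^2)))
    }
    for (i in seq_len(4L)) {
        dif <- spectraMatrix(out)[i, ] - 1
        ## recover the sinusoid by least squares over a dense frequency grid
        freqs <- seq(1 / 42, 1 / 14, length.out = 8001L)
        rss <- vapply(freqs, function(f) rssAt(f, dif)$rss, numeric(1))
        best <- rssAt(freqs[which.min(rss)], dif)
        expect_lt(best$rss / sum(dif^2), 1e-3)
        expect_gt(best$amp, 0.009); expect_lt(best$amp, 0.052)
    }
    ## step_fixed: all flagged rows break at the same channel indices
    devS <- DeviceProfile("F", 1350, 1650, nChannels = 60L,
                          artifactKinds = "step_fixed", artifactRate = 1)
    outS <- injectArtifacts(flat <- flatSpectraSet(n = 8L, K = 60L), devS, seed = 3L)
    jumpPos <- apply(spectraMatrix(outS), 1L, function(r) which(abs(diff(r)) > 1e-9))
    expect_true(all(vapply(seq_len(7L), function(i)
        identical(jumpPos[, i], jumpPos[, i + 1L]), logical(1))))
})
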