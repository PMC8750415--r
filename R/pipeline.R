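#' Unsupervised outlier screening of a spectra set
#'
#' Fits an unsupervised PCA (SIMCA machinery, cross-validated size) on all
#' rows and flags those beyond the score- or orthogonal-distance limits.
#' Rows beyond the `alphaRemove` limits (default 99 % confidence) are
#' removed; rows beyond the `alphaWarn` limits (default 95 %) are reported as
#' warnings but kept. Screening is run once — no iterative re-screening.
#'
#' @param spectra a [SpectraSet-class] (>= 10 rows).
#' @param alphaRemove significance of the removal limits (0.01 = 99 %).
#' @param alphaWarn significance of the warning limits (0.05 = 95 %).
#' @param nComponents PCA size; `NULL` for cross-validated selection.
#' @param seed seed for the selection folds.
#' @return List with `kept` (a [SpectraSet-class]) and `report` (a
#'   `data.frame` with one row per input spectrum: distances, which limit if
#'   any was violated, and whether the row was removed).
#' @export
screenOutliers <- function(spectra, alphaRemove = 0.01, alphaWarn = 0.05,
                           nComponents = NULL, seed = 1L) {
    stopifnot(is(spectra, "SpectraSet"))
    if (nSpectra(spectra) < 10L) stop("need at least 10 rows to screen")
    model <- fitSimca(spectra, nComponents = nComponents, alpha = alphaRemove,
                      seed = seed)
    pr <- project(model, spectra, working = TRUE)
    sdWarn <- t2Critical(model@N, model@nComponents, alphaWarn)
    odWarn <- as.numeric(odCritical(model@N, model@nComponents, model@K,
                                    alphaWarn, model@C0))
    removed <- !(pr$insideSD & pr$insideOD)
    if (all(removed)) stop("outlier screening removed every row")
    limit <- rep("none", length(removed))
    limit[pr$SD > sdWarn | pr$OD > odWarn] <- "warn95"
    limit[pr$SD > model@T2crit] <- "SD99"
    limit[pr$OD > model@ODcrit] <- "OD99"
    limit[pr$SD > model@T2crit & pr$OD > model@ODcrit] <- "SD99+OD99"
    report <- data.frame(
        row_id = rownames(spectraMatrix(spectra)),
        SD = pr$SD, OD = pr$OD, limit = limit, removed = removed,
        is_outlier_truth = spectraMeta(spectra)$is_outlier_truth,
        stringsAsFactors = FALSE)
    list(kept = spectra[, !removed], report = report)
}

#' Assemble a study run configuration
#'
#' @param design a [SampleDesign-class].
#' @param devices named list of [DeviceProfile-class] objects.
#' @param alpha significance level for SIMCA limits and the EJCR test.
#' @param maxComponents largest OPLS total component count to scan.
#' @param outDir output directory for artifacts, or `NULL` for none.
#' @param seed master seed (defaults to the design seed).
#' @return A `"runConfig"` list.
#' @export
runConfig <- function(design = SampleDesign(), devices = builtinDevices(),
                      alpha = 0.05, maxComponents = 8L, outDir = NULL,
                      seed = design@seed) {
    stopifnot(is(design, "SampleDesign"))
    if (is(devices, "DeviceProfile")) devices <- list(devices)
    for (d in devices) stopifnot(is(d, "DeviceProfile"))
    if (is.null(names(devices)) || any(!nzchar(names(devices))))
        names(devices) <- vapply(devices, deviceId, character(1))
    structure(list(design = design, devices = devices, alpha = alpha,
                   maxComponents = as.integer(maxComponents),
                   outDir = outDir, seed = as.integer(seed)),
              class = "runConfig")
}

## serializable view of a config, used for the manifest hash
.configDigestList <- function(config) {
    d <- config$design
    list(design = list(nCowSmp = d@nCowSmp, nBuffaloMix = d@nBuffaloMix,
                       adulterants = d@adulterants,
                       fraudLevels = d@fraudLevels,
                       nSpikedSmps = d@nSpikedSmps,
                       blendingModes = d@blendingModes,
                       nReplicates = d@nReplicates, seed = d@seed),
         devices = lapply(config$devices, function(x)
             list(id = x@deviceId, wl = c(x@wlMin, x@wlMax),
                  nChannels = x@nChannels, noiseSd = x@noiseSd,
                  noiseDf = x@noiseDf, artifactKinds = x@artifactKinds,
                  artifactRate = x@artifactRate)),
         alpha = config$alpha, maxComponents = config$maxComponents,
         seed = config$seed)
}

.hashConfig <- function(config) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(.configDigestList(config), tmp, auto_unbox = TRUE,
                         digits = NA)
    unname(md5sum(tmp))
}

## detection fraction per fraud level of one adulterant under a SIMCA model
.detectionSummary <- function(pr, meta, adulterant, levels) {
    out <- vapply(levels, function(lev) {
        sel <- meta$adulterant == adulterant & meta$fraud_level_pct == lev
        if (!any(sel)) return(NA_real_)
        mean(pr$verdict[sel] == "outlying")
    }, numeric(1))
    setNames(out, sprintf("det_%g", levels))
}

#' Run the end-to-end benchmark study
#'
#' For every device and blending mode: generate the designed spectra (with
#' artifacts), screen outliers once (99 % removal), fit the one-class SIMCA
#' model on the kept authentic cow SMP rows only (buffalo/cow mixes and
#' adulterated rows are projection-only), and project all kept rows. For
#' every device x adulterant x blending mode: average the replicates of each
#' spiked SMP at each concentration level (including the zero level from the
#' parent control sample), select and fit the OPLS model with sample-wise
#' cross-validation, and derive the figures of merit (EJCR verdict, LoD, LoQ
#' and their fraud-percent equivalents). Fully deterministic for a given
#' configuration and seed.
#'
#' @param config a `"runConfig"` list from [runConfig()].
#' @return List with `scorecard` (one `data.frame` row per device x
#'   adulterant x blending mode), `simca` (per device x mode summaries),
#'   `manifest` (config hash, seed, package version). When `config$outDir`
#'   is set, the scorecard (CSV + JSON), manifest, per-combination
#'   prediction CSVs and outlier reports are written there.
#' @export
runStudy <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    design <- config$design
    outDir <- config$outDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    scorecard <- list()
    simcaSummaries <- list()
    predictionTables <- list()
    for (devName in names(config$devices)) {
        device <- config$devices[[devName]]
        full <- generateSpectra(design, device)
        for (mode in design@blendingModes) {
            sel <- spectraMeta(full)$blending_mode == mode
            ss <- full[, sel]
            scr <- tryCatch(
                screenOutliers(ss, seed = substreamSeed(config$seed, "study",
                                                        utf8ToInt(devName))),
                error = function(e) stop(sprintf(
                    "stage screen_outliers failed for device %s / %s: %s",
                    devName, mode, conditionMessage(e))))
            kept <- scr$kept
            meta <- spectraMeta(kept)
            isTrain <- meta$adulterant == "none" & !grepl("^BUF", meta$smp_id)
            train <- kept[, isTrain]
            model <- tryCatch(
                fitSimca(train, alpha = config$alpha,
                         seed = substreamSeed(config$seed, "study",
                                              1000L + utf8ToInt(devName))),
                error = function(e) stop(sprintf(
                    "stage simca_fit failed for device %s / %s: %s",
                    devName, mode, conditionMessage(e))))
            pr <- project(model, kept)
            simcaSummaries[[paste(devName, mode, sep = "_")]] <- list(
                device = devName, blending = mode,
                nComponents = model@nComponents,
                trainRows = model@N,
                outlierRate = mean(scr$report$removed),
                controlFlagRate = mean(pr$verdict[isTrain] == "outlying"))
            for (ad in design@adulterants) {
                combo <- sprintf("%s_%s_%s", devName, ad, mode)
                res <- tryCatch(
                    .fitComboOpls(kept, meta, pr, ad, design, config),
                    error = function(e) stop(sprintf(
                        "stage opls failed for combination %s: %s",
                        combo, conditionMessage(e))))
                det <- .detectionSummary(pr, meta, ad, design@fraudLevels)
                scorecard[[combo]] <- data.frame(
                    device = devName, adulterant = ad, blending = mode,
                    t(det), nComponents = res$nComponents,
                    sizeCriterionMet = res$criterionMet,
                    R2 = res$r2, R2cv = res$r2cv,
                    RMSEc = res$rmseC, RMSEcv = res$rmseCv,
                    ejcrUnbiased = res$ejcr@unbiased,
                    lod = res$lod@lod, loq = res$lod@loq,
                    lodFraudPct = res$lod@lodFraudPct,
                    loqFraudPct = res$lod@loqFraudPct,
                    outlierRate = mean(scr$report$removed),
                    artifactTruthRate = mean(spectraMeta(ss)$is_outlier_truth),
                    stringsAsFactors = FALSE)
                predictionTables[[combo]] <- res$predictions
                if (!is.null(outDir))
                    utils::write.csv(res$predictions,
                        file.path(outDir, sprintf("predictions_%s.csv", combo)),
                        row.names = FALSE)
            }
            if (!is.null(outDir))
                utils::write.csv(scr$report,
                    file.path(outDir, sprintf("outliers_%s_%s.csv",
                                              devName, mode)),
                    row.names = FALSE)
        }
    }
    scorecard <- do.call(rbind, scorecard)
    rownames(scorecard) <- NULL
    manifest <- list(configHash = .hashConfig(config), seed = config$seed,
                     package = "specAuth",
                     version = as.character(utils::packageVersion("specAuth")))
    if (!is.null(outDir)) {
        utils::write.csv(scorecard, file.path(outDir, "scorecard.csv"),
                         row.names = FALSE)
        jsonlite::write_json(scorecard, file.path(outDir, "scorecard.json"),
                             dataframe = "rows", digits = NA)
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE)
    }
    list(scorecard = scorecard, simca = simcaSummaries,
         predictions = predictionTables, manifest = manifest)
}

## One adulterant x device x mode regression: replicate-average the spiked
## SMPs at their 4 levels (0 from the parent control sample), SNV the
## averaged spectra, select/fit OPLS with sample-wise CV, derive merit.
.fitComboOpls <- function(kept, meta, pr, adulterant, design, config) {
    parents <- sprintf("SMP%03d", seq_len(design@nSpikedSmps))
    rows <- (meta$adulterant == adulterant |
             (meta$adulterant == "none" & meta$smp_id %in% parents))
    M <- spectraMatrix(kept)[rows, , drop = FALSE]
    md <- meta[rows, , drop = FALSE]
    key <- paste(md$smp_id, md$dose_g_per_100g)
    ukey <- !duplicated(key)
    ## rowsum orders rows by sorted key; realign metadata accordingly
    ord <- sort(unique(key))
    cnt <- as.vector(table(key)[ord])
    X <- rowsum(M, key)[ord, , drop = FALSE] / cnt
    mdU <- md[ukey, , drop = FALSE][match(ord, key[ukey]), , drop = FALSE]
    y <- mdU$dose_g_per_100g
    groups <- mdU$smp_id
    Xp <- snv(X)
    selSize <- selectOplsSize(Xp, y, groups,
                              maxComponents = config$maxComponents)
    fit <- fitOpls(Xp, y, nOrtho = selSize$nOrtho)
    cvPred <- venetianCv(Xp, y, groups, nOrtho = selSize$nOrtho)
    rmseCv <- rmseCrossValidation(y, cvPred)
    ejcr <- ejcrTest(y, cvPred, alpha = config$alpha)
    lodRes <- lod(y, cvPred, alpha = config$alpha, beta = config$alpha,
                  adulterant = adulterant)
    list(nComponents = selSize$nComponents,
         criterionMet = selSize$criterionMet,
         r2 = fit@r2,
         r2cv = 1 - sum((y - cvPred)^2) / sum((y - mean(y))^2),
         rmseC = fit@rmseC, rmseCv = rmseCv,
         ejcr = ejcr, lod = lodRes,
         predictions = data.frame(sample_id = mdU$sample_id,
                                  smp_id = groups,
                                  fraud_level_pct = mdU$fraud_level_pct,
                                  y_ref = y, y_pred_cal = fit@fitted,
                                  y_pred_cv = cvPred,
                                  stringsAsFactors = FALSE))
}
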