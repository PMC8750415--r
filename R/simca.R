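#' SimcaModel: a fitted one-class SIMCA model
#'
#' PCA model of the authentic class with the statistics needed to judge new
#' samples: orthonormal loadings, training score variances, the pooled
#' residual standard deviation `s0`, the working-set correction factor `nu`,
#' and critical limits for the score distance (SD, Hotelling T2) and the
#' normalized orthogonal distance (OD) at significance level `alpha`.
#'
#' @slot nComponents number of principal components `C`.
#' @slot loadings K x C orthonormal loading matrix.
#' @slot scoreVar per-component training score variances `s2_tc`.
#' @slot scalingRecord column scaling applied at fit time (mean-centering +
#'   Pareto by default).
#' @slot snv logical; whether rows are SNV-transformed before scaling.
#' @slot s0 pooled residual standard deviation.
#' @slot nu working-set OD correction factor, `sqrt(N / (N - C - C0))`.
#' @slot N,K training rows and channels.
#' @slot C0 1 for column-centered data, 0 otherwise.
#' @slot alpha significance level of both limits.
#' @slot T2crit,ODcrit critical limits.
#' @slot odRegime which df rule produced `ODcrit` (`"largeK"` or
#'   `"fallback"`).
#' @slot varianceTable per-component explained (and, when size was selected by
#'   cross-validation, predicted) cumulative variance.
#' @slot trainSD,trainOD fitted distances of the (working-set) training rows;
#'   `trainOD` carries the `nu` correction.
#'
#' @exportClass SimcaModel
setClass("SimcaModel",
    representation(
        nComponents = "integer", loadings = "matrix", scoreVar = "numeric",
        scalingRecord = "ANY", snv = "logical", s0 = "numeric",
        nu = "numeric", N = "integer", K = "integer", C0 = "integer",
        alpha = "numeric", T2crit = "numeric", ODcrit = "numeric",
        odRegime = "character", varianceTable = "data.frame",
        trainSD = "numeric", trainOD = "numeric"
    )
)

setValidity("SimcaModel", function(object) {
    msg <- NULL
    if (object@nComponents < 1L) msg <- c(msg, "nComponents must be >= 1")
    if (any(object@scoreVar <= 0)) msg <- c(msg, "score variances must be > 0")
    if (object@s0 < 0) msg <- c(msg, "s0 must be >= 0")
    if (object@nu < 1) msg <- c(msg, "nu must be >= 1")
    if (!object@C0 %in% c(0L, 1L)) msg <- c(msg, "C0 must be 0 or 1")
    if (object@s0 > 0 && (object@T2crit <= 0 || object@ODcrit <= 0))
        msg <- c(msg, "critical limits must be > 0")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimcaModel", function(object) {
    cat(sprintf("SimcaModel: %d component(s), N = %d training rows, K = %d channels\n",
                object@nComponents, object@N, object@K))
    cat(sprintf("  s0 = %.4g, nu = %.4f, alpha = %.3g\n",
                object@s0, object@nu, object@alpha))
    cat(sprintf("  limits: T2 < %.4g, OD < %.4g (%s df rule)\n",
                object@T2crit, object@ODcrit, object@odRegime))
})

## rows of x in the model's preprocessed+scaled space
.simcaTransform <- function(model, X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    if (ncol(X) != model@K) stop("channel grid mismatch with model")
    if (model@snv) X <- snv(X)
    applyScalingRecord(model@scalingRecord, X)
}

.asMatrixInput <- function(x) {
    if (is(x, "SpectraSet")) return(spectraMatrix(x))
    if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

#' Critical limit for the score distance (Hotelling T2)
#'
#' `F(1 - alpha; C, N - C) * C * (N - 1) / (N - C)`: a training row with a
#' larger squared Mahalanobis score distance lies outside the `1 - alpha`
#' confidence region of the model.
#'
#' @param N training rows.
#' @param C model components.
#' @param alpha significance level in (0, 1).
#' @return The critical SD value.
#' @examples
#' t2Critical(25, 2, 0.05)
#' @export
t2Critical <- function(N, C, alpha = 0.05) {
    if (N <= C) stop("need N > C")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    qf(1 - alpha, C, N - C) * C * (N - 1) / (N - C)
}

#' Critical limit for the normalized orthogonal distance
#'
#' The OD boundary is `sqrt(F(1 - alpha; df1, df2))` with
#' `df2 = sqrt((N - C - C0) * (K - C))`. When `K > df2 > 100` the numerator
#' df follow the large-K rule
#' `df1 = (100 + sqrt(K - df2) - C) * N / (N - C - C0)`; otherwise the
#' uncorrected residual-df fallback `df1 = (K - C) * N / (N - C - C0)` is
#' used. The regime is attached as attribute `"regime"`.
#'
#' @param N training rows.
#' @param C model components.
#' @param K number of channels (`K > C`).
#' @param alpha significance level.
#' @param C0 1 for centered data (default), 0 otherwise.
#' @return Critical normalized OD, with attributes `df1`, `df2`, `regime`.
#' @examples
#' odCritical(50, 4, 256)
#' @export
odCritical <- function(N, C, K, alpha = 0.05, C0 = 1L) {
    if (K <= C) stop("need K > C")
    if (N <= C + C0) stop("need N > C + C0")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    df2 <- sqrt((N - C - C0) * (K - C))
    if (K > df2 && df2 > 100) {
        df1 <- (100 + sqrt(K - df2) - C) * N / (N - C - C0)
        regime <- "largeK"
    } else {
        df1 <- (K - C) * N / (N - C - C0)
        regime <- "fallback"
    }
    if (df1 <= 0 || df2 <= 0) stop("non-positive degrees of freedom")
    structure(sqrt(qf(1 - alpha, df1, df2)),
              df1 = df1, df2 = df2, regime = regime)
}

## PCA core on an already scaled matrix; sign convention: the largest-magnitude
## element of every loading is positive.
.fitPcaCore <- function(Xs, C) {
    N <- nrow(Xs); K <- ncol(Xs)
    if (C >= min(N - 1L, K) + 1L) stop("too many components for the data size")
    sv <- svd(Xs, nu = 0, nv = C)
    P <- sv$v
    flip <- vapply(seq_len(C), function(j) {
        v <- P[, j]; sign(v[which.max(abs(v))])
    }, numeric(1))
    P <- sweep(P, 2L, flip, "*")
    scores <- Xs %*% P
    list(loadings = P, scores = scores, d = sv$d)
}

#' Fit a one-class SIMCA model
#'
#' Builds the PCA model of the authentic class (SNV per row by default, then
#' mean-centering and Pareto scaling per column), via singular value
#' decomposition, and derives the SIMCA statistics: per-component score
#' variances, per-row residual standard deviations `s_i` (denominator
#' `K - C`), the pooled residual standard deviation `s0` (denominator
#' `(N - C - C0) * (K - C)`), the working-set correction
#' `nu = sqrt(N / (N - C - C0))`, and the critical limits [t2Critical()] and
#' [odCritical()] at `alpha`. When `nComponents` is `NULL` the model size is
#' chosen by [selectSimcaSize()].
#'
#' @param x [SpectraSet-class] or numeric matrix (spectra in rows).
#' @param nComponents number of components, or `NULL` for cross-validated
#'   selection.
#' @param alpha significance level for both limits.
#' @param snv apply SNV to rows before column scaling.
#' @param scaling `"pareto"` (default) or `"center"`.
#' @param sampleIds grouping key for cross-validated size selection (all
#'   replicates of a sample stay in one fold); defaults to the `sample_id`
#'   metadata when `x` is a [SpectraSet-class], else one group per row.
#' @param candidates candidate component counts for selection.
#' @param cvGroups number of cross-validation groups.
#' @param q2Tol relative eligibility tolerance on unpredicted variance:
#'   candidates with `1 - Q2 <= (1 - max(Q2)) * (1 + q2Tol)` compete on the
#'   gap.
#' @param seed seed for the random fold assignment.
#' @return A [SimcaModel-class].
#' @examples
#' X <- matrix(rnorm(300), 30, 10) + 5
#' m <- fitSimca(X, nComponents = 2, snv = FALSE)
#' m
#' @export
fitSimca <- function(x, nComponents = NULL, alpha = 0.05, snv = TRUE,
                     scaling = c("pareto", "center"), sampleIds = NULL,
                     candidates = NULL, cvGroups = 3L, seed = 1L,
                     q2Tol = 0.1) {
    scaling <- match.arg(scaling)
    X <- .asMatrixInput(x)
    if (is.null(sampleIds) && is(x, "SpectraSet"))
        sampleIds <- spectraMeta(x)$sample_id
    if (snv) X <- snv(X)
    N <- nrow(X); K <- ncol(X)
    sizeTable <- NULL
    if (is.null(nComponents)) {
        sel <- selectSimcaSize(X, candidates = candidates, cvGroups = cvGroups,
                               seed = seed, sampleIds = sampleIds, snv = FALSE,
                               scaling = scaling, q2Tol = q2Tol)
        nComponents <- sel$nComponents
        sizeTable <- sel$table
    }
    C <- as.integer(nComponents)
    C0 <- 1L
    if (N <= C + C0) stop("need N > C + C0 training rows")
    sc <- if (scaling == "pareto") paretoScale(X) else centerScale(X)
    core <- .fitPcaCore(sc$X, C)
    scoreVar <- apply(core$scores, 2L, var)
    E <- sc$X - core$scores %*% t(core$loadings)
    si2 <- rowSums(E^2) / (K - C)
    s0 <- sqrt(sum(E^2) / ((N - C - C0) * (K - C)))
    ## exact low-rank data: treat a numerically-zero pooled residual as zero
    if (s0 <= 1e-8 * sqrt(mean(sc$X^2))) s0 <- 0
    nu <- sqrt(N / (N - C - C0))
    ssTot <- sum(sc$X^2)
    r2cum <- cumsum(core$d^2)[seq_len(C)] / ssTot
    vt <- if (!is.null(sizeTable)) sizeTable else
        data.frame(nComponents = seq_len(C), R2cum = r2cum)
    trainSD <- colSums((t(core$scores)^2) / scoreVar)
    trainOD <- if (s0 > 0) sqrt(si2) / s0 * nu else rep(NaN, N)
    new("SimcaModel", nComponents = C, loadings = core$loadings,
        scoreVar = scoreVar, scalingRecord = sc$record, snv = snv,
        s0 = s0, nu = nu, N = as.integer(N), K = as.integer(K), C0 = C0,
        alpha = alpha, T2crit = t2Critical(N, C, alpha),
        ODcrit = if (s0 > 0) as.numeric(odCritical(N, C, K, alpha, C0)) else NaN,
        odRegime = if (s0 > 0) attr(odCritical(N, C, K, alpha, C0), "regime")
                   else "degenerate",
        varianceTable = vt, trainSD = unname(trainSD), trainOD = unname(trainOD))
}

#' Score distance (Hotelling T2) of rows under a SIMCA model
#'
#' Squared Mahalanobis distance in score space:
#' `SD_i = sum_c t_ic^2 / s2_tc` (training scores are centered, so their mean
#' is the origin).
#'
#' @param model a [SimcaModel-class].
#' @param x matrix / [SpectraSet-class] of query rows on the model's grid, in
#'   the same raw-absorbance space the model was fitted on.
#' @return Numeric vector of score distances.
#' @export
scoreDistance <- function(model, x) {
    Xs <- .simcaTransform(model, .asMatrixInput(x))
    T <- Xs %*% model@loadings
    colSums(t(T)^2 / model@scoreVar)
}

#' Normalized orthogonal distance of rows under a SIMCA model
#'
#' `OD_i = s_i / s0`, with `s_i^2 = sum_k e_ik^2 / (K - C)` the row residual
#' variance off the model plane and `s0` the pooled training residual standard
#' deviation. The correction factor `nu` is applied to working-set (training)
#' rows only: pass `working = TRUE` when the rows belong to the training set.
#'
#' @inheritParams scoreDistance
#' @param working logical; apply the `nu` correction (training rows).
#' @return Numeric vector of normalized orthogonal distances.
#' @export
orthogonalDistance <- function(model, x, working = FALSE) {
    if (model@s0 == 0)
        stop("degenerate exact-fit model: s0 = 0, OD undefined")
    Xs <- .simcaTransform(model, .asMatrixInput(x))
    E <- Xs - (Xs %*% model@loadings) %*% t(model@loadings)
    si <- sqrt(rowSums(E^2) / (model@K - model@nComponents))
    od <- si / model@s0
    if (working) od * model@nu else od
}

#' Cross-validated choice of the SIMCA model size
#'
#' Splits samples (not rows: all replicates of a sample share a fold) into
#' `cvGroups` random groups, and for each candidate component count computes
#' the cumulative explained variance R2 on the full data and the cumulative
#' predicted variance Q2 from the held-out projections. The chosen size
#' maximizes Q2 subject to the smallest explained-vs-predicted gap: among
#' candidates whose unpredicted variance `1 - Q2` is within a factor
#' `1 + q2Tol` of the best, the one with the smallest `R2 - Q2` wins;
#' remaining ties go to the smaller size. The relative form makes the rule
#' scale-free: on noise-dominated data most sizes tie and the gap criterion
#' collapses to a small model, while on highly structured data only
#' near-optimal sizes compete.
#'
#' @param x matrix or [SpectraSet-class] of authentic training rows.
#' @param candidates integer vector of candidate sizes (default `1:min(10,
#'   N - 2, K - 1)`).
#' @param cvGroups number of random groups (default 3).
#' @param seed seed for the fold draw.
#' @param sampleIds grouping key (replicate-leakage guard); default one group
#'   per row.
#' @param snv,scaling as in [fitSimca()].
#' @return List with `nComponents` and `table`
#'   (`nComponents`, `R2cum`, `Q2cum`, `gap`).
#' @export
selectSimcaSize <- function(x, candidates = NULL, cvGroups = 3L, seed = 1L,
                            sampleIds = NULL, snv = TRUE,
                            scaling = c("pareto", "center"), q2Tol = 0.1) {
    scaling <- match.arg(scaling)
    X <- .asMatrixInput(x)
    if (is.null(sampleIds) && is(x, "SpectraSet"))
        sampleIds <- spectraMeta(x)$sample_id
    if (snv) X <- snv(X)
    N <- nrow(X); K <- ncol(X)
    if (N < 6L) stop("need at least 6 rows to cross-validate the size")
    if (is.null(sampleIds)) sampleIds <- as.character(seq_len(N))
    if (is.null(candidates)) candidates <- seq_len(min(10L, N - 2L, K - 1L))
    candidates <- sort(unique(as.integer(candidates)))
    Cmax <- max(candidates)
    uid <- unique(sampleIds)
    fold <- withSubstream(seed, "cv", 0L,
        sample(rep_len(seq_len(cvGroups), length(uid))))
    foldOfRow <- fold[match(sampleIds, uid)]
    ## full-data explained variance
    scFull <- if (scaling == "pareto") paretoScale(X) else centerScale(X)
    svFull <- svd(scFull$X, nu = 0, nv = 0)
    r2 <- cumsum(svFull$d^2) / sum(svFull$d^2)
    press <- matrix(0, nrow = Cmax, ncol = cvGroups)
    sstot <- numeric(cvGroups)
    for (g in seq_len(cvGroups)) {
        tr <- foldOfRow != g
        if (sum(tr) < Cmax + 2L || sum(!tr) == 0L)
            stop("cross-validation folds too small for the candidate sizes")
        scTr <- if (scaling == "pareto") paretoScale(X[tr, , drop = FALSE])
                else centerScale(X[tr, , drop = FALSE])
        nvG <- min(Cmax, sum(tr) - 1L, K)
        P <- svd(scTr$X, nu = 0, nv = nvG)$v
        Xt <- applyScalingRecord(scTr$record, X[!tr, , drop = FALSE])
        sstot[g] <- sum(Xt^2)
        Tq <- Xt %*% P
        resid2 <- sum(Xt^2)
        for (C in seq_len(Cmax)) {
            if (C <= ncol(P)) resid2 <- resid2 - sum(Tq[, C]^2)
            press[C, g] <- resid2
        }
    }
    ## Predictive variance per remaining dimension: a plain projection PRESS
    ## shrinks mechanically with every extra loading, so it is normalized by
    ## the K - C dimensions left; under pure noise the curve is flat-to-
    ## decreasing instead of drifting upward.
    q2 <- 1 - (rowSums(press) / (K - seq_len(Cmax))) / (sum(sstot) / K)
    tab <- data.frame(nComponents = candidates,
                      R2cum = r2[candidates], Q2cum = q2[candidates])
    tab$gap <- tab$R2cum - tab$Q2cum
    if (all(!is.finite(tab$Q2cum))) stop("all candidate sizes degenerate")
    eligible <- (1 - tab$Q2cum) <= (1 - max(tab$Q2cum)) * (1 + q2Tol) + 1e-12
    sub <- tab[eligible, , drop = FALSE]
    best <- sub$nComponents[order(sub$gap, sub$nComponents)][1L]
    list(nComponents = as.integer(best), table = tab)
}

#' Project query spectra onto a SIMCA model
#'
#' Applies the model's stored preprocessing and scaling, computes the score
#' and orthogonal distances of every row, and flags them against the model's
#' critical limits. A row is `authentic` only when inside both limits.
#'
#' @param model a [SimcaModel-class].
#' @param queries [SpectraSet-class] or matrix on the model's wavelength grid.
#' @param working logical; treat the rows as working-set rows (applies the
#'   `nu` correction to OD).
#' @return A [S4Vectors::DataFrame] with columns `SD`, `OD`, `insideSD`,
#'   `insideOD`, `verdict`.
#' @export
setGeneric("project", function(model, queries, ...) standardGeneric("project"))

#' @rdname project
#' @param ... passed on.
#' @export
setMethod("project", "SimcaModel", function(model, queries, working = FALSE) {
    sd <- scoreDistance(model, queries)
    od <- orthogonalDistance(model, queries, working = working)
    insideSD <- sd <= model@T2crit
    insideOD <- od <= model@ODcrit
    DataFrame(SD = sd, OD = od, insideSD = insideSD, insideOD = insideOD,
              verdict = ifelse(insideSD & insideOD, "authentic", "outlying"),
              row.names = rownames(.asMatrixInput(queries)))
})

#' Persist / restore a SIMCA model as text files
#'
#' The model is written as `<prefix>_model.json` (scalars, limits, score
#' variances, scaling record) and `<prefix>_loadings.csv` (K x C loading
#' matrix). `readSimcaModel()` reconstructs an identical model; projections
#' from the restored model match the original exactly.
#'
#' @param model a [SimcaModel-class].
#' @param prefix path prefix for the two files.
#' @return `writeSimcaModel()` returns the two paths invisibly;
#'   `readSimcaModel()` the restored [SimcaModel-class].
#' @export
writeSimcaModel <- function(model, prefix) {
    stopifnot(is(model, "SimcaModel"))
    rec <- model@scalingRecord
    js <- list(nComponents = model@nComponents, scoreVar = model@scoreVar,
               snv = model@snv, s0 = model@s0, nu = model@nu, N = model@N,
               K = model@K, C0 = model@C0, alpha = model@alpha,
               T2crit = model@T2crit, ODcrit = model@ODcrit,
               odRegime = model@odRegime,
               scaling = list(center = rec$center, divisor = rec$divisor,
                              zeroSd = rec$zeroSd, kind = rec$kind),
               trainSD = model@trainSD, trainOD = model@trainOD,
               varianceTable = model@varianceTable)
    fs <- paste0(prefix, c("_model.json", "_loadings.csv"))
    jsonlite::write_json(js, fs[1L], auto_unbox = TRUE, digits = NA)
    utils::write.csv(model@loadings, fs[2L], row.names = FALSE)
    invisible(fs)
}

#' @rdname writeSimcaModel
#' @export
readSimcaModel <- function(prefix) {
    fs <- paste0(prefix, c("_model.json", "_loadings.csv"))
    js <- jsonlite::read_json(fs[1L], simplifyVector = TRUE)
    P <- as.matrix(utils::read.csv(fs[2L]))
    dimnames(P) <- NULL
    rec <- structure(list(center = js$scaling$center,
                          divisor = js$scaling$divisor,
                          zeroSd = as.logical(js$scaling$zeroSd),
                          kind = js$scaling$kind), class = "scalingRecord")
    new("SimcaModel", nComponents = as.integer(js$nComponents),
        loadings = P, scoreVar = js$scoreVar, scalingRecord = rec,
        snv = js$snv, s0 = js$s0, nu = js$nu, N = as.integer(js$N),
        K = as.integer(js$K), C0 = as.integer(js$C0), alpha = js$alpha,
        T2crit = js$T2crit, ODcrit = js$ODcrit, odRegime = js$odRegime,
        varianceTable = as.data.frame(js$varianceTable),
        trainSD = js$trainSD, trainOD = js$trainOD)
}
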