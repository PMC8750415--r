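#' OplsModel: single-response OPLS regression model
#'
#' Partial least squares regression with orthogonal signal correction: a
#' sequence of `nOrtho` components capturing systematic X-variation orthogonal
#' to the response is removed before a single predictive PLS component is
#' fitted. Predictors are mean-centered (after any row preprocessing done
#' upstream); the response is mean-centered and not scaled.
#'
#' @slot nOrtho number of orthogonal components.
#' @slot predWeights,predLoadings,predCoef weight, loading and regression
#'   coefficient of the predictive component.
#' @slot orthoWeights,orthoLoadings K x nOrtho matrices of the orthogonal
#'   components (0 columns when `nOrtho = 0`).
#' @slot xCenter,yCenter centering vectors.
#' @slot fitted calibration predictions for the training rows.
#' @slot rmseC,rmseCv,r2 calibration error (denominator N - 2),
#'   cross-validation error (denominator N; `NA` until a CV is attached) and
#'   coefficient of determination.
#'
#' @exportClass OplsModel
setClass("OplsModel",
    representation(
        nOrtho = "integer", predWeights = "numeric", predLoadings = "numeric",
        predCoef = "numeric", orthoWeights = "matrix",
        orthoLoadings = "matrix", xCenter = "numeric", yCenter = "numeric",
        fitted = "numeric", rmseC = "numeric", rmseCv = "numeric",
        r2 = "numeric"
    )
)

setMethod("show", "OplsModel", function(object) {
    cat(sprintf("OplsModel: 1 predictive + %d orthogonal component(s)\n",
                object@nOrtho))
    cat(sprintf("  RMSEc = %.4g, RMSEcv = %s, R2 = %.4f\n", object@rmseC,
                ifelse(is.na(object@rmseCv), "NA", sprintf("%.4g", object@rmseCv)),
                object@r2))
})

#' Root mean squared error of calibration
#'
#' `sqrt(sum((yRef - yPred)^2) / (N - 2))`; the two degrees of freedom account
#' for the predictive component and the centering of an OPLS fit.
#'
#' @param yRef,yPred reference and predicted responses, equal length `N > 2`.
#' @return RMSEc in response units.
#' @examples
#' rmseCalibration(c(1, 2, 3, 4), c(2, 1, 4, 3))  # sqrt(4/2)
#' @export
rmseCalibration <- function(yRef, yPred) {
    if (length(yRef) != length(yPred)) stop("length mismatch")
    n <- length(yRef)
    if (n <= 2L) stop("need N > 2 for the N - 2 denominator")
    sqrt(sum((yRef - yPred)^2) / (n - 2))
}

#' Root mean squared error of cross-validation
#'
#' `sqrt(sum((yRef - yPredCv)^2) / N)` over out-of-fold predictions.
#'
#' @param yRef,yPredCv reference values and cross-validated predictions.
#' @return RMSEcv in response units.
#' @examples
#' rmseCrossValidation(c(3, 4), c(0, 0))  # sqrt(25/2)
#' @export
rmseCrossValidation <- function(yRef, yPredCv) {
    if (length(yRef) != length(yPredCv)) stop("length mismatch")
    if (!length(yRef)) stop("empty input")
    sqrt(mean((yRef - yPredCv)^2))
}

#' Fit an OPLS model
#'
#' Implements the standard single-response O-PLS recipe: iteratively, the
#' PLS weight `w = X'y / |X'y|` is computed, the loading of the corresponding
#' score is split into its projection on `w` and an orthogonal remainder
#' `w_o`, and the orthogonal component `t_o = X w_o` is deflated from `X`;
#' after `nOrtho` such steps one predictive PLS component is fitted on the
#' filtered matrix. With `nOrtho = 0` the model is exactly a one-component
#' PLS1 fit.
#'
#' @param X numeric matrix of predictors (rows = samples).
#' @param y numeric response with at least 2 distinct values.
#' @param nOrtho number of orthogonal components (>= 0, less than the rank
#'   of the centered `X`).
#' @return An [OplsModel-class] (with `rmseCv = NA`; see [venetianCv()]).
#' @export
fitOpls <- function(X, y, nOrtho = 0L) {
    X <- as.matrix(X); y <- as.numeric(y)
    if (nrow(X) != length(y)) stop("rows of X must match length of y")
    if (length(unique(y)) < 2L) stop("constant response")
    nOrtho <- as.integer(nOrtho)
    if (nOrtho < 0L) stop("nOrtho must be >= 0")
    xc <- colMeans(X); yc <- mean(y)
    Xd <- sweep(X, 2L, xc, "-"); yd <- y - yc
    rk <- qr(Xd)$rank
    if (nOrtho >= rk) stop("nOrtho must be smaller than rank(X)")
    K <- ncol(X)
    Wo <- matrix(0, K, 0); Po <- matrix(0, K, 0)
    for (j in seq_len(nOrtho)) {
        w <- drop(crossprod(Xd, yd)); w <- w / sqrt(sum(w^2))
        t <- drop(Xd %*% w)
        p <- drop(crossprod(Xd, t)) / sum(t^2)
        wo <- p - sum(w * p) * w
        no <- sqrt(sum(wo^2))
        if (no < 1e-12) break  # no y-orthogonal structure left
        wo <- wo / no
        to <- drop(Xd %*% wo)
        po <- drop(crossprod(Xd, to)) / sum(to^2)
        Xd <- Xd - to %o% po
        Wo <- cbind(Wo, wo); Po <- cbind(Po, po)
    }
    w <- drop(crossprod(Xd, yd)); w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    q <- sum(yd * t) / sum(t^2)
    fitted <- yc + q * t
    ssTot <- sum((y - yc)^2)
    r2 <- 1 - sum((y - fitted)^2) / ssTot
    rmseC <- if (length(y) > 2L) rmseCalibration(y, fitted) else 0
    new("OplsModel", nOrtho = ncol(Wo), predWeights = w, predLoadings = p,
        predCoef = q, orthoWeights = Wo, orthoLoadings = Po,
        xCenter = xc, yCenter = yc, fitted = fitted,
        rmseC = rmseC, rmseCv = NA_real_, r2 = r2)
}

#' Predict from an OPLS model
#'
#' Centers new rows, sequentially removes the stored orthogonal components,
#' and applies the predictive component.
#'
#' @param object an [OplsModel-class].
#' @param newdata matrix of rows on the same variables as the training `X`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
setMethod("predict", "OplsModel", function(object, newdata, ...) {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object@xCenter)) stop("variable mismatch")
    Xd <- sweep(X, 2L, object@xCenter, "-")
    for (j in seq_len(object@nOrtho)) {
        to <- drop(Xd %*% object@orthoWeights[, j])
        Xd <- Xd - to %o% object@orthoLoadings[, j]
    }
    drop(object@yCenter + object@predCoef * (Xd %*% object@predWeights))
})

#' Sample-wise (Venetian blinds) cross-validation
#'
#' Each group — in the study design, one SMP with all its concentration
#' levels — is removed exactly once; the model is refitted on the remaining
#' groups and the held-out rows are predicted. Deterministic: the iteration
#' order is the order of first appearance of the group labels.
#'
#' @param X,y predictors and response as in [fitOpls()].
#' @param groups grouping labels, one per row; at least 2 distinct groups.
#' @param nOrtho orthogonal components for each refit.
#' @return Numeric vector of out-of-fold predictions, aligned with the rows
#'   of `X`.
#' @export
venetianCv <- function(X, y, groups, nOrtho = 0L) {
    X <- as.matrix(X)
    if (length(groups) != nrow(X)) stop("one group label per row required")
    ug <- unique(groups)
    if (length(ug) < 2L) stop("need at least 2 groups")
    pred <- numeric(nrow(X))
    for (g in ug) {
        out <- groups == g
        fit <- fitOpls(X[!out, , drop = FALSE], y[!out], nOrtho = nOrtho)
        pred[out] <- predict(fit, X[out, , drop = FALSE])
    }
    pred
}

#' Choose the OPLS model size from the RMSEcv curve
#'
#' Scans total component counts (`1 + nOrtho` for `nOrtho = 0, 1, ...`) and
#' applies the stabilization rule: the chosen size is the smallest whose
#' RMSEcv lies within `stabTol` (default 5 %) of the minimum of the centered
#' 3-point moving average of the RMSEcv curve, while differing from RMSEc by
#' less than `calGapMax` (default 30 %). When no size satisfies both
#' conditions the RMSEcv argmin is returned with `criterionMet = FALSE`.
#'
#' @param X,y,groups as in [venetianCv()].
#' @param maxComponents largest total component count to scan.
#' @param stabTol stabilization band around the smoothed minimum (relative).
#' @param calGapMax maximum allowed `(RMSEcv - RMSEc) / RMSEc`.
#' @return List with `nComponents` (total), `nOrtho`, `criterionMet`, and
#'   `curves` (`data.frame`: `nComponents`, `RMSEc`, `RMSEcv`, `R2`).
#' @export
selectOplsSize <- function(X, y, groups, maxComponents = 8L,
                           stabTol = 0.05, calGapMax = 0.30) {
    if (maxComponents < 1L) stop("maxComponents must be >= 1")
    X <- as.matrix(X)
    rk <- qr(sweep(X, 2L, colMeans(X), "-"))$rank
    maxOrtho <- min(maxComponents - 1L, rk - 1L)
    sizes <- 0:maxOrtho
    rmseC <- rmseCv <- r2 <- numeric(length(sizes))
    for (i in seq_along(sizes)) {
        fit <- fitOpls(X, y, nOrtho = sizes[i])
        cv <- venetianCv(X, y, groups, nOrtho = sizes[i])
        rmseC[i] <- fit@rmseC
        rmseCv[i] <- rmseCrossValidation(y, cv)
        r2[i] <- fit@r2
    }
    ## centered 3-point moving average (ends use the available neighbours);
    ## stabilization is judged on the smoothed curve, so a single low raw
    ## value inside a non-stabilized region does not qualify
    ma <- vapply(seq_along(rmseCv), function(i) {
        idx <- max(1L, i - 1L):min(length(rmseCv), i + 1L)
        mean(rmseCv[idx])
    }, numeric(1))
    stabMin <- min(ma)
    ok <- ma <= (1 + stabTol) * stabMin &
        (rmseCv - rmseC) / rmseC < calGapMax
    if (any(ok)) {
        pick <- which(ok)[1L]; met <- TRUE
    } else {
        pick <- which.min(rmseCv); met <- FALSE
    }
    list(nComponents = sizes[pick] + 1L, nOrtho = sizes[pick],
         criterionMet = met,
         curves = data.frame(nComponents = sizes + 1L, RMSEc = rmseC,
                             RMSEcv = rmseCv, R2 = r2))
}
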