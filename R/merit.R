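#' EjcrResult: elliptical joint confidence region bias test
#'
#' Result of the EJCR test for simultaneous intercept = 0 and slope = 1 of
#' the univariate regression of predicted on reference values. The model is
#' declared unbiased when the ideal point (0, 1) lies inside the elliptical
#' `1 - alpha` joint confidence region of the estimated intercept and slope.
#'
#' @slot aHat,bHat estimated intercept and slope.
#' @slot mse mean squared error of the univariate regression (denominator
#'   N - 2).
#' @slot fCrit F quantile at (2, N - 2, 1 - alpha).
#' @slot quadFormAtIdeal value of the EJCR quadratic form at (0, 1).
#' @slot alpha significance level.
#' @slot n number of points.
#' @slot unbiased flag: `quadFormAtIdeal <= 2 * mse * fCrit`.
#'
#' @exportClass EjcrResult
setClass("EjcrResult",
    representation(aHat = "numeric", bHat = "numeric", mse = "numeric",
                   fCrit = "numeric", quadFormAtIdeal = "numeric",
                   alpha = "numeric", n = "integer", unbiased = "logical"))

setMethod("show", "EjcrResult", function(object) {
    cat(sprintf("EJCR bias test (alpha = %.3g, N = %d)\n",
                object@alpha, object@n))
    cat(sprintf("  intercept = %.4g, slope = %.4g\n", object@aHat, object@bHat))
    cat(sprintf("  Q(0,1) = %.4g vs 2*MSE*F = %.4g -> %s\n",
                object@quadFormAtIdeal, 2 * object@mse * object@fCrit,
                if (object@unbiased) "UNBIASED" else "BIASED"))
})

#' EJCR test for joint intercept/slope bias
#'
#' Fits `yPred = a + b * yRef` by least squares and evaluates the joint
#' confidence-region quadratic form
#' `N*(aHat - a)^2 + 2*sum(yRef)*(aHat - a)*(bHat - b) +
#'  sum(yRef^2)*(bHat - b)^2`
#' at the ideal point `(a, b) = (0, 1)` against the boundary value
#' `2 * MSE * F(2, N - 2; 1 - alpha)`, where MSE is the regression mean
#' squared error with denominator `N - 2`. Under an unbiased predictor with
#' Gaussian errors the test has exact level `alpha`.
#'
#' @param yRef reference values (not constant), length `N > 2`.
#' @param yPred predicted values (typically cross-validated predictions).
#' @param alpha significance level.
#' @return An [EjcrResult-class].
#' @examples
#' ejcrTest(1:10, 1:10 + rnorm(10, 0, 0.1))
#' @export
ejcrTest <- function(yRef, yPred, alpha = 0.05) {
    yRef <- as.numeric(yRef); yPred <- as.numeric(yPred)
    n <- length(yRef)
    if (length(yPred) != n) stop("length mismatch")
    if (n <= 2L) stop("need N > 2")
    if (length(unique(yRef)) < 2L) stop("constant reference values")
    fit <- lm(yPred ~ yRef)
    aHat <- unname(coef(fit)[1L]); bHat <- unname(coef(fit)[2L])
    mse <- sum(residuals(fit)^2) / (n - 2)
    quad <- n * aHat^2 + 2 * sum(yRef) * aHat * (bHat - 1) +
        sum(yRef^2) * (bHat - 1)^2
    fCrit <- qf(1 - alpha, 2, n - 2)
    new("EjcrResult", aHat = aHat, bHat = bHat, mse = mse, fCrit = fCrit,
        quadFormAtIdeal = quad, alpha = alpha, n = as.integer(n),
        unbiased = quad <= 2 * mse * fCrit)
}

#' LodResult: pseudo-univariate limit of detection
#'
#' @slot lod limit of detection, response (dose) units.
#' @slot loq limit of quantification, `3 * lod` exactly.
#' @slot lodFraudPct,loqFraudPct the same limits on the fraud-percent scale
#'   (`NA` when no adulterant context was given).
#' @slot rmseU univariate-regression residual error (denominator N - 2).
#' @slot h0 leverage at zero analyte concentration.
#' @slot delta detection-decision factor `Delta(alpha, beta; nu)`.
#' @slot bHat regression slope used for the conversion to concentration.
#' @slot alpha,beta false-positive and false-negative probabilities.
#' @slot n number of points.
#'
#' @exportClass LodResult
setClass("LodResult",
    representation(lod = "numeric", loq = "numeric", lodFraudPct = "numeric",
                   loqFraudPct = "numeric", rmseU = "numeric", h0 = "numeric",
                   delta = "numeric", bHat = "numeric", alpha = "numeric",
                   beta = "numeric", n = "integer"))

setMethod("show", "LodResult", function(object) {
    cat(sprintf("LoD = %.3g, LoQ = %.3g (dose units; alpha = %.3g, beta = %.3g, N = %d)\n",
                object@lod, object@loq, object@alpha, object@beta, object@n))
    if (is.finite(object@lodFraudPct))
        cat(sprintf("  fraud scale: LoD = %.3g %%, LoQ = %.3g %%\n",
                    object@lodFraudPct, object@loqFraudPct))
    cat(sprintf("  RMSEu = %.3g, h0 = %.3g, Delta = %.3g, slope = %.3g\n",
                object@rmseU, object@h0, object@delta, object@bHat))
})

## Delta(alpha, beta; nu): for nu <= 100 the exact non-centrality parameter of
## the non-central t distribution (the delta for which a level-alpha t test
## has power 1 - beta); for larger nu the sum of the two Student quantiles.
deltaFactor <- function(alpha, beta, nu) {
    if (nu > 100) return(qt(1 - alpha, nu) + qt(1 - beta, nu))
    tcrit <- qt(1 - alpha, nu)
    f <- function(d) pt(tcrit, nu, ncp = d) - beta
    upper <- (qt(1 - alpha, nu) + qt(1 - beta, nu)) * 4 + 10
    uniroot(f, c(1e-8, upper), tol = 1e-10)$root
}

#' Pseudo-univariate limit of detection
#'
#' Computes `LoD = Delta(alpha, beta; nu) * RMSEu * sqrt(1 + 1/N + h0) /
#' bHat` from the univariate regression of (cross-validated) predictions on
#' reference concentrations, with `RMSEu` the regression residual error
#' (denominator `N - 2`), `h0 = mean(yRef)^2 / sum((yRef - mean(yRef))^2)`
#' the leverage at zero concentration (the most conservative point), and
#' `Delta` the detection-decision factor: the exact non-central-t
#' non-centrality for `nu = N - 2 <= 100`, the sum of the two Student
#' quantiles (`~ 3.29` at `alpha = beta = 0.05`) for larger `nu`.
#'
#' @param yRef reference concentrations (dose units).
#' @param yPredCv predictions (cross-validated by default in the pipeline).
#' @param bHat regression slope; computed from the data when `NULL`.
#' @param alpha,beta false-positive / false-negative probabilities.
#' @param adulterant,composition optional context to also express the limits
#'   on the fraud-percent scale via [fraudPctConversion()].
#' @return A [LodResult-class]; `loq` is exactly `3 * lod`.
#' @export
lod <- function(yRef, yPredCv, bHat = NULL, alpha = 0.05, beta = 0.05,
                adulterant = NULL, composition = defaultComposition()) {
    yRef <- as.numeric(yRef); yPredCv <- as.numeric(yPredCv)
    n <- length(yRef)
    if (length(yPredCv) != n) stop("length mismatch")
    if (n <= 2L) stop("need N > 2")
    if (sd(yPredCv) == 0)
        stop("constant predictions: slope must be non-zero")
    fit <- lm(yPredCv ~ yRef)
    if (is.null(bHat)) bHat <- unname(coef(fit)[2L])
    if (!is.finite(bHat) || abs(bHat) < 1e-10 * sd(yPredCv) / sd(yRef))
        stop("slope must be non-zero")
    rmseU <- sqrt(sum(residuals(fit)^2) / (n - 2))
    ybar <- mean(yRef)
    h0 <- ybar^2 / sum((yRef - ybar)^2)
    delta <- deltaFactor(alpha, beta, n - 2)
    lodVal <- delta * rmseU * sqrt(1 + 1 / n + h0) / abs(bHat)
    fp <- if (!is.null(adulterant))
        fraudPctConversion(lodVal, adulterant, composition) else NA_real_
    new("LodResult", lod = lodVal, loq = 3 * lodVal, lodFraudPct = fp,
        loqFraudPct = 3 * fp, rmseU = rmseU, h0 = h0, delta = delta,
        bHat = bHat, alpha = alpha, beta = beta, n = as.integer(n))
}

#' Limit of quantification
#'
#' `LoQ = 3 * LoD`, on both the dose and the fraud-percent scales.
#'
#' @param lodResult a [LodResult-class] (or a bare LoD number).
#' @return Numeric LoQ (dose units) for a bare number; for a
#'   [LodResult-class] the stored `loq`.
#' @examples
#' loq(0.82)  # 2.46
#' @export
loq <- function(lodResult) {
    if (is(lodResult, "LodResult")) return(lodResult@loq)
    3 * as.numeric(lodResult)
}
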