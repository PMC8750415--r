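#' Standard normal variate (SNV)
#'
#' Centers each spectrum to mean 0 and scales it to unit sample standard
#' deviation (n-1 denominator). SNV removes per-spectrum additive offsets and
#' multiplicative scatter exactly: `snv(a*x + b) = snv(x)` for any `a > 0`.
#'
#' @param x numeric vector (one spectrum) or matrix (spectra in rows).
#' @return Transformed vector/matrix of the same shape.
#' @examples
#' snv(c(1, 2, 3))   # -1 0 1
#' @export
snv <- function(x) {
    if (is.matrix(x)) {
        out <- t(apply(x, 1L, snv))
        dimnames(out) <- dimnames(x)
        return(out)
    }
    if (length(x) < 2L) stop("SNV needs at least 2 channels")
    s <- sd(x)
    if (!is.finite(s) || s == 0)
        stop("degenerate input: constant spectrum has no SNV transform")
    (x - mean(x)) / s
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Replaces each point by the `deriv`-th derivative of a local least-squares
#' polynomial fit of order `polyorder` over a centered window of `window`
#' points. Near the edges the same window polynomial is evaluated at
#' asymmetric positions, so the output length equals the input length.
#' Derivatives are taken with respect to the channel index unless `delta`
#' (the grid spacing) is supplied.
#'
#' @param x numeric vector (one spectrum) or matrix (spectra in rows).
#' @param window odd window length, `> polyorder`.
#' @param polyorder polynomial order, `>= deriv`.
#' @param deriv derivative order (0 = smoothing).
#' @param delta abscissa spacing used to scale derivatives.
#' @return Filtered vector/matrix, same shape as `x`.
#' @examples
#' savitzkyGolay(2 * (1:20), window = 7, polyorder = 2, deriv = 1)  # all 2
#' @export
savitzkyGolay <- function(x, window, polyorder = 2L, deriv = 0L, delta = 1) {
    window <- as.integer(window); polyorder <- as.integer(polyorder)
    deriv <- as.integer(deriv)
    if (window %% 2L != 1L) stop("window must be odd")
    if (window <= polyorder) stop("window must exceed polyorder")
    if (deriv > polyorder) stop("deriv must not exceed polyorder")
    if (deriv < 0L) stop("deriv must be >= 0")
    if (is.matrix(x)) {
        out <- t(apply(x, 1L, savitzkyGolay, window = window,
                       polyorder = polyorder, deriv = deriv, delta = delta))
        dimnames(out) <- dimnames(x)
        return(out)
    }
    if (length(x) < window) stop("spectrum shorter than the filter window")
    signal::sgolayfilt(x, p = polyorder, n = window, m = deriv, ts = delta)
}

#' Pareto scaling
#'
#' Mean-centers each column of a matrix and divides it by the square root of
#' its sample standard deviation. Columns with zero standard deviation are
#' centered only and recorded as degenerate. The returned record can be
#' re-applied to new data and inverted.
#'
#' @param X numeric matrix (rows = spectra, columns = variables).
#' @return List with `X` (the scaled matrix) and `record` (a
#'   `"scalingRecord"`: column means, scale divisors, zero-sd flags).
#' @seealso [applyScalingRecord()], [invertScalingRecord()]
#' @export
paretoScale <- function(X) {
    X <- as.matrix(X)
    mu <- colMeans(X)
    s <- colSds(X)
    if (any(!is.finite(s))) stop("column sd must be finite")
    zero <- s == 0
    div <- ifelse(zero, 1, sqrt(s))
    record <- structure(list(center = mu, divisor = div, zeroSd = zero,
                             kind = "pareto"), class = "scalingRecord")
    list(X = applyScalingRecord(record, X), record = record)
}

## mean-center only, same record machinery
centerScale <- function(X) {
    X <- as.matrix(X)
    mu <- colMeans(X)
    record <- structure(list(center = mu, divisor = rep(1, length(mu)),
                             zeroSd = rep(FALSE, length(mu)),
                             kind = "center"), class = "scalingRecord")
    list(X = applyScalingRecord(record, X), record = record)
}

#' Apply / invert a stored scaling record
#'
#' @param record a `"scalingRecord"` from [paretoScale()].
#' @param X matrix (or vector treated as one row) with the same columns as
#'   the data the record was built on.
#' @return The transformed (or back-transformed) matrix.
#' @export
applyScalingRecord <- function(record, X) {
    stopifnot(inherits(record, "scalingRecord"))
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    if (ncol(X) != length(record$center)) stop("column mismatch with record")
    sweep(sweep(X, 2L, record$center, "-"), 2L, record$divisor, "/")
}

#' @rdname applyScalingRecord
#' @export
invertScalingRecord <- function(record, X) {
    stopifnot(inherits(record, "scalingRecord"))
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    sweep(sweep(X, 2L, record$divisor, "*"), 2L, record$center, "+")
}

#' Apply an ordered preprocessing specification
#'
#' Runs a chain of row-wise spectral filters over a matrix or
#' [SpectraSet-class]. Each step is a list with an `op` field: `"snv"` or
#' `"sg"` (with `window`, `polyorder`, `deriv`). Column-wise model scaling
#' (mean-centering, Pareto) is deliberately not part of the filter chain: it
#' belongs to model fitting.
#'
#' @param x matrix (spectra in rows) or [SpectraSet-class].
#' @param steps list of step specifications, e.g.
#'   `list(list(op = "snv"), list(op = "sg", window = 11, polyorder = 2, deriv = 1))`.
#' @return Object of the same class as `x`, filtered.
#' @export
applyPreprocess <- function(x, steps = list(list(op = "snv"))) {
    if (is(x, "SpectraSet")) {
        M <- applyPreprocess(spectraMatrix(x), steps)
        out <- SpectraSet(M, wavelengths(x), spectraMeta(x))
        metadata(out) <- metadata(x)
        return(out)
    }
    X <- as.matrix(x)
    for (st in steps) {
        X <- switch(st$op,
            snv = snv(X),
            sg = savitzkyGolay(X, window = st$window,
                               polyorder = if (is.null(st$polyorder)) 2L else st$polyorder,
                               deriv = if (is.null(st$deriv)) 0L else st$deriv),
            stop(sprintf("unknown preprocessing op '%s'", st$op)))
    }
    X
}
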