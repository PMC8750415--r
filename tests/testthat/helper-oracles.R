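## Independent brute-force oracles used to check the fast implementations.

## Savitzky-Golay by explicit per-window polynomial least squares, with
## asymmetric windows at the edges (same convention the filter promises).
sgOracle <- function(x, window, polyorder, deriv = 0L, delta = 1) {
    n <- length(x)
    half <- (window - 1L) %/% 2L
    out <- numeric(n)
    for (i in seq_len(n)) {
        lo <- max(1L, min(i - half, n - window + 1L))
        hi <- lo + window - 1L
        idx <- lo:hi
        z <- (idx - i) * delta
        fit <- lm.fit(outer(z, 0:polyorder, "^"), x[idx])
        out[i] <- fit$coefficients[deriv + 1L] * factorial(deriv)
    }
    out
}

## One-component PLS1 predictions in closed form.
pls1Oracle <- function(X, y, newdata = X) {
    xc <- colMeans(X); yc <- mean(y)
    Xd <- sweep(X, 2L, xc, "-"); yd <- y - yc
    w <- drop(crossprod(Xd, yd)); w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    q <- sum(yd * t) / sum(t^2)
    drop(yc + q * (sweep(newdata, 2L, xc, "-") %*% w))
}

## Score distance through an explicit inverse-covariance quadratic form in
## score space (diagonal covariance by construction of PCA scores, but the
## oracle builds and inverts the full empirical covariance).
mahalanobisOracle <- function(scoresTrain, scoresQuery) {
    S <- cov(scoresTrain)
    ctr <- colMeans(scoresTrain)
    stats::mahalanobis(scoresQuery, center = ctr, cov = S)
}

## EJCR membership by direct evaluation of the quadratic form.
ejcrOracle <- function(yRef, yPred, a = 0, b = 1, alpha = 0.05) {
    n <- length(yRef)
    fit <- lm(yPred ~ yRef)
    aH <- coef(fit)[1]; bH <- coef(fit)[2]
    lhs <- n * (aH - a)^2 + 2 * sum(yRef) * (aH - a) * (bH - b) +
        sum(yRef^2) * (bH - b)^2
    unname(lhs <= 2 * sum(residuals(fit)^2) / (n - 2) * qf(1 - alpha, 2, n - 2))
}
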