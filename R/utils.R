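## Seed plumbing: one master integer seed is split into purpose-specific
## substreams so that composition, scatter, noise, artifacts and CV grouping
## are independently reproducible. The mix is a fixed LCG-style hash kept
## below 2^31 - 1.

.SUBSTREAMS <- c(library = 1L, composition = 2L, scatter = 3L, noise = 4L,
                 artifacts = 5L, cv = 6L, study = 7L)

substreamSeed <- function(seed, purpose, id = 0L) {
    p <- .SUBSTREAMS[[purpose]]
    x <- (as.numeric(seed) %% 2147483647) * 48271
    x <- (x + p * 30269 + as.numeric(id) * 69621) %% 2147483629
    as.integer(x) + 1L
}

## Evaluate expr with the RNG seeded from a substream, restoring the caller's
## RNG state afterwards.
withSubstream <- function(seed, purpose, id, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(substreamSeed(seed, purpose, id))
    expr
}

gaussianBand <- function(grid, center, width, amplitude) {
    amplitude * exp(-0.5 * ((grid - center) / width)^2)
}

## column-wise sample sd without the matrixStats dependency
colSds <- function(X) {
    n <- nrow(X)
    if (n < 2L) return(rep(NA_real_, ncol(X)))
    mu <- colMeans(X)
    sqrt(colSums((X - rep(mu, each = n))^2) / (n - 1))
}
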