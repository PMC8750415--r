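## Synthetic spectra generation. The physical picture is Beer-Lambert linear
## mixing of pure-component curves on top of a particle-size-driven baseline,
## followed by measurement effects: per-replicate multiplicative/additive
## scatter (bag-location packing), per-replicate detector noise with
## heterogeneous variance, and device-specific artifacts.

## wet-blend indirect-response coefficients for ammonium sulfate: upon
## dissolution and re-spray-drying the salt alters moisture retention and
## particle structure, so the latent matrix factors shift with dose
.WET_AS_MOISTURE_PER_G <- 1.5   # g/100 g moisture per g/100 g dose
.WET_AS_PARTICLE_PER_G <- 0.20  # particle factor units per g/100 g dose
.WET_AS_CRYST_PER_G <- 0.8      # crystallinity score units per g/100 g dose

## Fixed diffuse-reflectance pseudo-absorbance baseline. Per-sample particle
## size enters additively through the scatter-shape derivative .particleShape
## (the wavelength-dependent part of a baseline rescaling), so the sample
## population stays linear in its latent factors; purely multiplicative
## pathlength effects live in the per-replicate scatter term, which SNV
## removes exactly.
.baseline <- function(grid) {
    x <- (grid - 1500) / 1000
    0.35 + 0.25 * x + 0.15 * x^2
}

.particleShape <- function(grid) {
    x <- (grid - 1500) / 1000
    0.25 * x + 0.15 * x^2
}

## Sample table: one row per distinct sample per blending mode.
buildSampleTable <- function(design) {
    modes <- design@blendingModes
    cow <- sprintf("SMP%03d", seq_len(design@nCowSmp))
    buf <- if (design@nBuffaloMix > 0)
        sprintf("BUF%02d", seq_len(design@nBuffaloMix)) else character()
    parents <- cow[seq_len(design@nSpikedSmps)]
    out <- list()
    for (mode in modes) {
        tab <- data.frame(
            sample_id = c(cow, buf), smp_id = c(cow, buf),
            adulterant = "none", fraud_level_pct = 0,
            blending_mode = mode, stringsAsFactors = FALSE)
        for (ad in design@adulterants)
            for (lev in design@fraudLevels)
                tab <- rbind(tab, data.frame(
                    sample_id = sprintf("%s_%s_%g", parents, ad, lev),
                    smp_id = parents, adulterant = ad,
                    fraud_level_pct = lev, blending_mode = mode,
                    stringsAsFactors = FALSE))
        out[[mode]] <- tab
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    tab$dose_g_per_100g <- 0
    for (ad in design@adulterants) {
        sel <- tab$adulterant == ad
        tab$dose_g_per_100g[sel] <-
            doseForFraudLevel(ad, tab$fraud_level_pct[sel])
    }
    tab
}

## Per-SMP base compositions (g/100 g) and particle factor, shared across
## devices and blending modes; drawn from the composition substream only.
drawCompositions <- function(design) {
    withSubstream(design@seed, "composition", 0L, {
        nC <- design@nCowSmp; nB <- design@nBuffaloMix
        ids <- c(sprintf("SMP%03d", seq_len(nC)),
                 if (nB > 0) sprintf("BUF%02d", seq_len(nB)))
        data.frame(
            smp_id = ids,
            protein = c(rnorm(nC, 33.7, 1.2), rnorm(nB, 35.5, 1.0)),
            lactose = c(rnorm(nC, 52.0, 1.5), rnorm(nB, 49.0, 1.5)),
            fat = pmax(c(rnorm(nC, 0.8, 0.15), rnorm(nB, 1.5, 0.2)), 0.05),
            moisture = pmax(c(rnorm(nC, 4.0, 0.7), rnorm(nB, 4.2, 0.7)), 0.5),
            particle = pmax(rnorm(nC + nB, 1.0, 0.12), 0.5),
            heat = c(rnorm(nC, 0, 1), rnorm(nB, 0.5, 1)),
            whey = c(rnorm(nC, 0, 1), rnorm(nB, -1, 1)),
            crystallinity = rnorm(nC + nB, 0, 1),
            stringsAsFactors = FALSE)
    })
}

## Noise-free sample spectra matrix (samples x channels).
sampleSpectra <- function(tab, comps, lib, grid) {
    idx <- match(tab$smp_id, comps$smp_id)
    moisture <- comps$moisture[idx]
    particle <- comps$particle[idx]
    wet <- tab$blending_mode == "wet"
    ## re-spray-dried powder: slightly compacted, marginally moister
    particle[wet] <- particle[wet] * 1.05
    moisture[wet] <- moisture[wet] + 0.3
    ## indirect response of ammonium sulfate in the liquid phase
    ias <- wet & tab$adulterant == "ammonium_sulfate"
    cryst <- comps$crystallinity[idx]
    moisture[ias] <- moisture[ias] + .WET_AS_MOISTURE_PER_G * tab$dose_g_per_100g[ias]
    particle[ias] <- particle[ias] + .WET_AS_PARTICLE_PER_G * tab$dose_g_per_100g[ias]
    cryst[ias] <- cryst[ias] + .WET_AS_CRYST_PER_G * tab$dose_g_per_100g[ias]
    S <- rep(1, nrow(tab)) %o% .baseline(grid) +
        (particle - 1) %o% .particleShape(grid) +
        comps$protein[idx] %o% lib$protein +
        comps$lactose[idx] %o% lib$lactose +
        comps$fat[idx] %o% lib$fat +
        moisture %o% lib$moisture +
        comps$heat[idx] %o% lib$heat +
        comps$whey[idx] %o% lib$whey +
        cryst %o% lib$crystallinity
    for (ad in unique(tab$adulterant)) {
        if (ad == "none") next
        sel <- tab$adulterant == ad
        S[sel, ] <- S[sel, ] + tab$dose_g_per_100g[sel] %o% lib[[ad]]
    }
    rownames(S) <- tab$sample_id
    S
}

#' Generate a synthetic spectra set for one device
#'
#' Expands a [SampleDesign-class] into replicate spectra on the device's
#' wavelength grid: Beer-Lambert mixing of seeded pure-component curves with
#' per-SMP compositions, a particle-size baseline, wet-blend matrix shifts
#' (including the indirect dose response of ammonium sulfate in the liquid
#' phase), per-replicate multiplicative/additive scatter, per-replicate
#' Gaussian noise with heterogeneous variance, and (optionally) the device's
#' artifact taxonomy via [injectArtifacts()]. Sample compositions depend only
#' on the design seed, so the same samples are "measured" consistently across
#' devices. Fully deterministic for a given design seed and device.
#'
#' @param design a [SampleDesign-class].
#' @param device a [DeviceProfile-class].
#' @param scatter logical; draw per-replicate scatter terms (multiplicative
#'   lognormal, sd 0.05 on the log scale; additive Gaussian, sd 0.01 AU).
#' @param noise logical; draw per-replicate channel noise (sd
#'   `noiseSd(device)` scaled by a per-replicate inverse-chi-square variance
#'   factor with `noiseDf` df).
#' @param artifacts logical; inject device artifacts at the device's rate.
#' @return A [SpectraSet-class] with `samplesPerMode(design) * nModes *
#'   nReplicates` spectra.
#' @examples
#' d <- SampleDesign(nCowSmp = 5L, nBuffaloMix = 0L, adulterants = character(),
#'                   nSpikedSmps = 0L, blendingModes = "dry",
#'                   nReplicates = 3L, seed = 7L)
#' generateSpectra(d, builtinDevices()$A)
#' @export
generateSpectra <- function(design, device, scatter = TRUE, noise = TRUE,
                            artifacts = TRUE) {
    stopifnot(is(design, "SampleDesign"), is(device, "DeviceProfile"))
    grid <- deviceGrid(device)
    lib <- buildComponentLibrary(grid, seed = design@seed)
    tab <- buildSampleTable(design)
    comps <- drawCompositions(design)
    S <- sampleSpectra(tab, comps, lib, grid)
    nRep <- design@nReplicates
    nS <- nrow(tab)
    K <- length(grid)
    rowOf <- rep(seq_len(nS), each = nRep)
    X <- S[rowOf, , drop = FALSE]
    devKey <- utf8ToInt(substr(device@deviceId, 1L, 1L))
    if (scatter) {
        withSubstream(design@seed, "scatter", devKey, {
            m <- rlnorm(nS * nRep, 0, 0.05)
            a <- rnorm(nS * nRep, 0, 0.01)
            X <- X * m + a
        })
    }
    if (noise && device@noiseSd > 0) {
        withSubstream(design@seed, "noise", devKey, {
            u <- if (is.finite(device@noiseDf))
                sqrt(device@noiseDf / rchisq(nS * nRep, device@noiseDf))
            else rep(1, nS * nRep)
            ## speckle-like noise: scales with the spectral contrast of the
            ## measured sample (sd over channels, referenced to 0.05 AU), as
            ## diffuse-reflectance noise does; noiseSd is the sd at reference
            ## contrast
            contrast <- apply(S, 1L, sd)[rowOf] / 0.05
            X <- X + matrix(rnorm(nS * nRep * K), nS * nRep, K) *
                (device@noiseSd * u * contrast)
        })
    }
    meta <- tab[rowOf, , drop = FALSE]
    meta$replicate_idx <- rep(seq_len(nRep), times = nS)
    meta$device_id <- device@deviceId
    meta$is_outlier_truth <- FALSE
    rownames(X) <- sprintf("%s_%s_%s_r%02d", device@deviceId,
                           meta$blending_mode, meta$sample_id,
                           meta$replicate_idx)
    rownames(meta) <- rownames(X)
    ss <- SpectraSet(X, grid, meta)
    if (artifacts && device@artifactRate > 0 && length(device@artifactKinds))
        ss <- injectArtifacts(ss, device, seed = design@seed)
    ss
}

#' Inject device artifacts into a spectra set
#'
#' Applies the device's artifact taxonomy to randomly selected replicates and
#' flags them in `is_outlier_truth`:
#' * `intensity_offset` — a broad positive absorbance bump (uneven powder
#'   packing / large particles);
#' * `fringe` — a high-frequency sinusoidal interference pattern across the
#'   whole range (multiple reflections on the packaging film);
#' * `step_fixed` — level shifts at channel positions fixed per device;
#' * `step_random` — level shifts at per-row random positions and sizes.
#'
#' A no-op when the device's `artifactRate` is 0.
#'
#' @param spectra a [SpectraSet-class].
#' @param device a [DeviceProfile-class].
#' @param seed integer seed (artifact substream).
#' @return The modified [SpectraSet-class] with truth flags set on affected
#'   rows (and only those).
#' @export
injectArtifacts <- function(spectra, device, seed = 1L) {
    stopifnot(is(spectra, "SpectraSet"), is(device, "DeviceProfile"))
    if (device@artifactRate <= 0 || !length(device@artifactKinds))
        return(spectra)
    X <- spectraMatrix(spectra)
    grid <- wavelengths(spectra)
    K <- ncol(X)
    n <- nrow(X)
    fixedBreaks <- unique(pmax(2L, round(K * c(1, 2) / 3)))
    devKey <- utf8ToInt(substr(device@deviceId, 1L, 1L))
    hit <- logical(n)
    withSubstream(seed, "artifacts", devKey, {
        hit <- runif(n) < device@artifactRate
        for (i in which(hit)) {
            kind <- sample(device@artifactKinds, 1L)
            if (kind == "intensity_offset") {
                ctr <- runif(1, min(grid), max(grid))
                wid <- 0.2 * (max(grid) - min(grid))
                X[i, ] <- X[i, ] + gaussianBand(grid, ctr, wid,
                                                runif(1, 0.1, 0.4))
            } else if (kind == "fringe") {
                period <- runif(1, 15, 40)
                phase <- runif(1, 0, 2 * pi)
                X[i, ] <- X[i, ] + runif(1, 0.01, 0.05) *
                    sin(2 * pi * (grid - grid[1]) / period + phase)
            } else if (kind == "step_fixed") {
                for (b in fixedBreaks)
                    X[i, b:K] <- X[i, b:K] + runif(1, -0.3, 0.3)
            } else { # step_random
                nb <- sample(1:3, 1L)
                pos <- sample(2:K, nb)
                for (b in pos)
                    X[i, b:K] <- X[i, b:K] + runif(1, -0.3, 0.3)
            }
        }
    })
    meta <- spectraMeta(spectra)
    meta$is_outlier_truth <- meta$is_outlier_truth | hit
    out <- SpectraSet(X, grid, meta)
    metadata(out) <- metadata(spectra)
    out
}
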