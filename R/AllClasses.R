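#' @include specAuth-package.R
NULL

## ---------------------------------------------------------------------------
## DeviceProfile
## ---------------------------------------------------------------------------

#' DeviceProfile: one miniature NIR sensor
#'
#' Describes a sensor by its wavelength window, channel count, replicate noise
#' model and the spectral-artifact taxonomy it is prone to. Eight built-in
#' profiles (`A`..`H`, see [builtinDevices()]) cover the technology classes of
#' the benchmarked devices: multichannel optical filtering (A), grating with an
#' InGaAs array (B, C), MEMS DLP (D), MEMS FT-IR (E) and MEMS Fabry-Perot
#' interferometers (F, G, H).
#'
#' @slot deviceId single letter label.
#' @slot wlMin,wlMax wavelength window in nm.
#' @slot nChannels number of spectral channels on the grid.
#' @slot noiseSd replicate noise standard deviation, absorbance units.
#' @slot noiseDf degrees of freedom of the optional per-replicate
#'   noise-variance heterogeneity (scaled inverse-chi-square); the default
#'   `Inf` means homogeneous replicate noise.
#' @slot artifactKinds subset of `"intensity_offset"`, `"fringe"`,
#'   `"step_fixed"`, `"step_random"`.
#' @slot artifactRate probability that a replicate carries an artifact.
#'
#' @exportClass DeviceProfile
setClass("DeviceProfile",
    representation(
        deviceId = "character",
        wlMin = "numeric",
        wlMax = "numeric",
        nChannels = "integer",
        noiseSd = "numeric",
        noiseDf = "numeric",
        artifactKinds = "character",
        artifactRate = "numeric"
    )
)

.ARTIFACT_KINDS <- c("intensity_offset", "fringe", "step_fixed", "step_random")

setValidity("DeviceProfile", function(object) {
    msg <- NULL
    if (length(object@deviceId) != 1L || !nzchar(object@deviceId))
        msg <- c(msg, "deviceId must be a single non-empty label")
    if (!(object@wlMin < object@wlMax))
        msg <- c(msg, "wlMin must be < wlMax")
    if (object@nChannels < 16L)
        msg <- c(msg, "nChannels must be >= 16")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (!(object@noiseDf > 2))
        msg <- c(msg, "noiseDf must be > 2 (or Inf)")
    if (!all(object@artifactKinds %in% .ARTIFACT_KINDS))
        msg <- c(msg, sprintf("artifactKinds must be among: %s",
                              paste(.ARTIFACT_KINDS, collapse = ", ")))
    if (object@artifactRate < 0 || object@artifactRate > 1)
        msg <- c(msg, "artifactRate must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Construct a DeviceProfile
#'
#' @param deviceId single-letter device label.
#' @param wlMin,wlMax wavelength window (nm).
#' @param nChannels number of channels (>= 16).
#' @param noiseSd replicate noise sd in absorbance units.
#' @param noiseDf df of the replicate noise-variance heterogeneity; `Inf`
#'   disables it.
#' @param artifactKinds character vector of artifact kinds.
#' @param artifactRate per-replicate artifact probability.
#' @return A [DeviceProfile-class] object.
#' @examples
#' DeviceProfile("X", 900, 1700, nChannels = 64L)
#' @export
DeviceProfile <- function(deviceId, wlMin, wlMax, nChannels = 64L,
                          noiseSd = 0.003, noiseDf = Inf,
                          artifactKinds = character(), artifactRate = 0) {
    new("DeviceProfile", deviceId = as.character(deviceId),
        wlMin = as.numeric(wlMin), wlMax = as.numeric(wlMax),
        nChannels = as.integer(nChannels), noiseSd = as.numeric(noiseSd),
        noiseDf = as.numeric(noiseDf),
        artifactKinds = as.character(artifactKinds),
        artifactRate = as.numeric(artifactRate))
}

setMethod("show", "DeviceProfile", function(object) {
    cat(sprintf("DeviceProfile '%s': %g-%g nm, %d channels\n",
                object@deviceId, object@wlMin, object@wlMax, object@nChannels))
    cat(sprintf("  noise sd %.4g AU (heterogeneity df %s)\n", object@noiseSd,
                format(object@noiseDf)))
    if (length(object@artifactKinds))
        cat(sprintf("  artifacts: %s at rate %.3g\n",
                    paste(object@artifactKinds, collapse = ", "),
                    object@artifactRate))
    else cat("  artifacts: none\n")
})

#' Wavelength grid of a device
#'
#' @param device a [DeviceProfile-class].
#' @return Numeric vector of `nChannels` equally spaced wavelengths (nm).
#' @export
deviceGrid <- function(device) {
    stopifnot(is(device, "DeviceProfile"))
    seq(device@wlMin, device@wlMax, length.out = device@nChannels)
}

#' Device accessor
#' @param x a [DeviceProfile-class].
#' @return The device label.
#' @export
deviceId <- function(x) x@deviceId

## ---------------------------------------------------------------------------
## SampleDesign
## ---------------------------------------------------------------------------

#' SampleDesign: the sample and adulteration plan
#'
#' Encodes the study design: a collection of authentic cow skimmed-milk-powder
#' (SMP) samples, a few buffalo/cow mixes, and spiked samples prepared from a
#' designated subset of control SMPs at several fraud levels, in dry- and/or
#' wet-blended variants, each sample measured in replicate. The defaults
#' reproduce the benchmark design: 70 cow SMPs + 3 buffalo/cow mixes + 3
#' adulterants x 10 spiked SMPs x 3 fraud levels = 163 samples per blending
#' mode, 10 replicates each.
#'
#' @slot nCowSmp number of authentic cow SMP samples.
#' @slot nBuffaloMix number of buffalo/cow mix samples.
#' @slot adulterants character vector of adulterant names.
#' @slot fraudLevels fraud levels in percent (strictly positive).
#' @slot nSpikedSmps number of control SMPs spiked per adulterant.
#' @slot blendingModes subset of `c("dry", "wet")`.
#' @slot nReplicates replicate spectra per sample.
#' @slot seed integer master seed; all randomness is derived from it through
#'   purpose-specific substreams.
#'
#' @exportClass SampleDesign
setClass("SampleDesign",
    representation(
        nCowSmp = "integer",
        nBuffaloMix = "integer",
        adulterants = "character",
        fraudLevels = "numeric",
        nSpikedSmps = "integer",
        blendingModes = "character",
        nReplicates = "integer",
        seed = "integer"
    )
)

.ADULTERANTS <- c("ammonium_sulfate", "semicarbazide", "cornstarch")

setValidity("SampleDesign", function(object) {
    msg <- NULL
    if (object@nCowSmp < 0L) msg <- c(msg, "nCowSmp must be >= 0")
    if (object@nBuffaloMix < 0L) msg <- c(msg, "nBuffaloMix must be >= 0")
    if (!all(object@adulterants %in% .ADULTERANTS))
        msg <- c(msg, sprintf("adulterants must be among: %s",
                              paste(.ADULTERANTS, collapse = ", ")))
    if (any(object@fraudLevels <= 0))
        msg <- c(msg, "fraud levels must be strictly positive")
    if (object@nSpikedSmps > object@nCowSmp)
        msg <- c(msg, "nSpikedSmps cannot exceed nCowSmp")
    if (length(object@adulterants) && object@nSpikedSmps < 1L)
        msg <- c(msg, "nSpikedSmps must be >= 1 when adulterants are present")
    if (!length(object@blendingModes) ||
        !all(object@blendingModes %in% c("dry", "wet")))
        msg <- c(msg, "blendingModes must be a non-empty subset of dry/wet")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SampleDesign
#'
#' @param nCowSmp,nBuffaloMix,adulterants,fraudLevels,nSpikedSmps,blendingModes,nReplicates,seed
#'   see [SampleDesign-class]; defaults give the 163-samples-per-mode
#'   benchmark design.
#' @return A [SampleDesign-class] object.
#' @examples
#' d <- SampleDesign()
#' samplesPerMode(d)   # 163
#' @export
SampleDesign <- function(nCowSmp = 70L, nBuffaloMix = 3L,
                         adulterants = .ADULTERANTS,
                         fraudLevels = c(0.5, 5.0, 10.0),
                         nSpikedSmps = 10L,
                         blendingModes = c("dry", "wet"),
                         nReplicates = 10L, seed = 1L) {
    new("SampleDesign", nCowSmp = as.integer(nCowSmp),
        nBuffaloMix = as.integer(nBuffaloMix),
        adulterants = as.character(adulterants),
        fraudLevels = as.numeric(fraudLevels),
        nSpikedSmps = as.integer(nSpikedSmps),
        blendingModes = as.character(blendingModes),
        nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Design arithmetic
#'
#' `samplesPerMode()` counts distinct samples per blending mode;
#' `designSummary()` expands the arithmetic of a design over a device list:
#' samples per mode, total spectra, averaged rows per regression fit, and the
#' size of the regression model grid (devices x adulterants x modes).
#'
#' @param design a [SampleDesign-class].
#' @param devices list of [DeviceProfile-class] objects.
#' @return `samplesPerMode()`: integer. `designSummary()`: named list with
#'   `samplesPerMode`, `nModes`, `nDevices`, `totalSpectra`, `oplsRowsPerFit`
#'   (spiked SMPs x (1 + number of fraud levels)) and `nOplsModels`.
#' @examples
#' designSummary(SampleDesign(), builtinDevices())$totalSpectra  # 26080
#' @export
samplesPerMode <- function(design) {
    stopifnot(is(design, "SampleDesign"))
    design@nCowSmp + design@nBuffaloMix +
        length(design@adulterants) * design@nSpikedSmps *
            length(design@fraudLevels)
}

#' @rdname samplesPerMode
#' @export
designSummary <- function(design, devices = builtinDevices()) {
    if (is(devices, "DeviceProfile")) devices <- list(devices)
    spm <- samplesPerMode(design)
    nModes <- length(design@blendingModes)
    list(samplesPerMode = spm,
         nModes = nModes,
         nDevices = length(devices),
         totalSpectra = length(devices) * spm * nModes * design@nReplicates,
         oplsRowsPerFit = design@nSpikedSmps * (1L + length(design@fraudLevels)),
         nOplsModels = length(devices) * length(design@adulterants) * nModes)
}

setMethod("show", "SampleDesign", function(object) {
    cat(sprintf(
        "SampleDesign: %d cow + %d buffalo/cow SMPs, %d adulterant(s) x %d spiked x %d level(s)\n",
        object@nCowSmp, object@nBuffaloMix, length(object@adulterants),
        object@nSpikedSmps, length(object@fraudLevels)))
    cat(sprintf("  modes: %s; %d replicates; %d samples per mode; seed %d\n",
                paste(object@blendingModes, collapse = "+"),
                object@nReplicates, samplesPerMode(object), object@seed))
})

## ---------------------------------------------------------------------------
## SpectraSet
## ---------------------------------------------------------------------------

#' SpectraSet: a set of replicate spectra with metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding an
#' absorbance assay (channels in rows, spectra in columns), the wavelength
#' grid in `rowData`, and per-spectrum metadata (sample id, parent SMP id,
#' device, replicate index, adulterant, fraud level, dose, blending mode,
#' artifact truth flag) in `colData`. User-facing accessors present spectra in
#' the conventional chemometrics orientation (rows = spectra).
#'
#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
    msg <- NULL
    wl <- rowData(object)$wavelength_nm
    if (is.null(wl)) return("rowData must carry 'wavelength_nm'")
    if (is.unsorted(wl, strictly = TRUE))
        msg <- c(msg, "wavelengths must be strictly increasing")
    need <- c("sample_id", "replicate_idx", "is_outlier_truth")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, sprintf("colData lacks: %s", paste(miss, collapse = ", ")))
    else {
        ok <- colData(object)$is_outlier_truth
        clean <- assay(object)[, !ok, drop = FALSE]
        if (length(clean) && !all(is.finite(clean)))
            msg <- c(msg, "non-finite absorbance in rows not flagged as outliers")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, rows = spectra, columns = channels.
#' @param wavelengths strictly increasing wavelength grid (nm), one per column
#'   of `absorbance`.
#' @param meta `data.frame` / `DataFrame` of per-spectrum metadata with at
#'   least `sample_id` and `replicate_idx`; `is_outlier_truth` is added
#'   (all `FALSE`) when absent.
#' @return A [SpectraSet-class].
#' @examples
#' ss <- SpectraSet(matrix(rnorm(40), 4, 10), seq(900, 1700, length.out = 10),
#'                  data.frame(sample_id = paste0("S", 1:4), replicate_idx = 1L))
#' nSpectra(ss)
#' @export
SpectraSet <- function(absorbance, wavelengths, meta) {
    absorbance <- as.matrix(absorbance)
    meta <- as(meta, "DataFrame")
    if (is.null(meta$is_outlier_truth))
        meta$is_outlier_truth <- rep(FALSE, nrow(meta))
    if (nrow(meta) != nrow(absorbance))
        stop("meta must have one row per spectrum")
    if (length(wavelengths) != ncol(absorbance))
        stop("one wavelength per absorbance column required")
    ids <- if (!is.null(rownames(absorbance))) rownames(absorbance) else
        sprintf("row%05d", seq_len(nrow(absorbance)))
    se <- SummarizedExperiment(
        assays = list(absorbance = t(absorbance)),
        rowData = DataFrame(wavelength_nm = as.numeric(wavelengths)),
        colData = meta)
    colnames(se) <- ids
    new("SpectraSet", se)
}

#' SpectraSet accessors
#'
#' `wavelengths()` returns the grid in nm; `spectraMatrix()` the absorbance
#' matrix with spectra in rows; `spectraMeta()` the per-spectrum metadata as a
#' `data.frame`; `nSpectra()` the number of spectra.
#'
#' @param x a [SpectraSet-class].
#' @return See description.
#' @export
wavelengths <- function(x) rowData(x)$wavelength_nm

#' @rdname wavelengths
#' @export
spectraMatrix <- function(x) t(assay(x, "absorbance"))

#' @rdname wavelengths
#' @export
spectraMeta <- function(x) as.data.frame(colData(x))

#' @rdname wavelengths
#' @export
nSpectra <- function(x) ncol(x)

setMethod("show", "SpectraSet", function(object) {
    md <- spectraMeta(object)
    cat(sprintf("SpectraSet: %d spectra x %d channels (%g-%g nm)\n",
                ncol(object), nrow(object), min(wavelengths(object)),
                max(wavelengths(object))))
    if (!is.null(md$device_id))
        cat(sprintf("  devices: %s\n",
                    paste(unique(md$device_id), collapse = ", ")))
    cat(sprintf("  samples: %d; artifact-truth rows: %d\n",
                length(unique(md$sample_id)), sum(md$is_outlier_truth)))
})
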