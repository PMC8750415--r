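#' Write / read a SpectraSet as a delimited text pair
#'
#' A set is persisted as two UTF-8 CSV files with header rows and `.` decimal
#' separators: `<prefix>_spectra.csv` (first column `row_id`, remaining
#' columns wavelength-labelled absorbances) and `<prefix>_meta.csv`
#' (`row_id`-keyed metadata).
#'
#' @param x a [SpectraSet-class].
#' @param prefix path prefix for the two files.
#' @return `writeSpectraSet()` returns the two file paths invisibly;
#'   `readSpectraSet()` returns the reconstructed [SpectraSet-class].
#' @export
writeSpectraSet <- function(x, prefix) {
    stopifnot(is(x, "SpectraSet"))
    M <- spectraMatrix(x)
    wl <- wavelengths(x)
    spec <- data.table::data.table(row_id = rownames(M))
    for (j in seq_along(wl)) spec[[sprintf("wl_%.12g", wl[j])]] <- M[, j]
    meta <- data.table::data.table(row_id = rownames(M), spectraMeta(x))
    fs <- paste0(prefix, c("_spectra.csv", "_meta.csv"))
    data.table::fwrite(spec, fs[1L])
    data.table::fwrite(meta, fs[2L])
    invisible(fs)
}

#' @rdname writeSpectraSet
#' @export
readSpectraSet <- function(prefix) {
    fs <- paste0(prefix, c("_spectra.csv", "_meta.csv"))
    spec <- data.table::fread(fs[1L], data.table = FALSE)
    meta <- data.table::fread(fs[2L], data.table = FALSE)
    if (!identical(spec$row_id, meta$row_id))
        stop("spectra and meta files disagree on row ids")
    M <- as.matrix(spec[, -1L, drop = FALSE])
    wl <- as.numeric(sub("^wl_", "", colnames(M)))
    dimnames(M) <- list(spec$row_id, NULL)
    rownames(meta) <- meta$row_id
    SpectraSet(M, wl, meta[, setdiff(colnames(meta), "row_id"), drop = FALSE])
}

#' Read a study configuration from YAML or JSON
#'
#' The file mirrors the [SampleDesign()] fields under `design`, plus optional
#' `devices` (letters of built-in profiles), `alpha`, `maxComponents`,
#' `outDir` and `seed`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A run configuration list, see [runConfig()].
#' @export
readRunConfig <- function(path) {
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    dn <- cfg$design
    design <- SampleDesign(
        nCowSmp = dn$nCowSmp %||% 70L,
        nBuffaloMix = dn$nBuffaloMix %||% 3L,
        adulterants = dn$adulterants %||% .ADULTERANTS,
        fraudLevels = dn$fraudLevels %||% c(0.5, 5, 10),
        nSpikedSmps = dn$nSpikedSmps %||% 10L,
        blendingModes = dn$blendingModes %||% c("dry", "wet"),
        nReplicates = dn$nReplicates %||% 10L,
        seed = cfg$seed %||% dn$seed %||% 1L)
    devices <- builtinDevices()
    if (!is.null(cfg$devices)) devices <- devices[unlist(cfg$devices)]
    runConfig(design, devices, alpha = cfg$alpha %||% 0.05,
              maxComponents = cfg$maxComponents %||% 8L,
              outDir = cfg$outDir, seed = cfg$seed %||% design@seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
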