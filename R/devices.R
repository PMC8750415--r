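#' Built-in device profiles
#'
#' The eight benchmark sensor profiles. Wavelength windows follow the devices
#' under study: A 740-1070 nm (multichannel optical filtering, Si array),
#' B/C/D 900-1700 nm (grating InGaAs, grating InGaAs, MEMS DLP), E
#' 1300-2500 nm (MEMS FT-IR), F 1350-1650, G 1550-1950 and H 1750-2150 nm
#' (MEMS Fabry-Perot). Channel counts, noise levels and artifact taxonomies
#' are package choices representative of each technology class: the filter
#' device has few, wide channels; grating devices a denser grid; the
#' interferometer devices intermediate grids with more replicate noise.
#' Artifact kinds mirror the anomalies each class exhibits: broad intensity
#' offsets (A), high-frequency interference fringes (B, C, D), step breaks at
#' fixed wavelengths (F) and steps at random positions and sizes (G, H).
#'
#' @return Named list of eight [DeviceProfile-class] objects, `A` to `H`.
#' @examples
#' builtinDevices()[["A"]]
#' @export
builtinDevices <- function() {
    list(
        A = DeviceProfile("A", 740, 1070, nChannels = 32L, noiseSd = 0.00025,
                          artifactKinds = "intensity_offset",
                          artifactRate = 0.02),
        B = DeviceProfile("B", 900, 1700, nChannels = 125L, noiseSd = 0.0020,
                          artifactKinds = "fringe", artifactRate = 0.05),
        C = DeviceProfile("C", 900, 1700, nChannels = 125L, noiseSd = 0.0020,
                          artifactKinds = "fringe", artifactRate = 0.08),
        D = DeviceProfile("D", 900, 1700, nChannels = 125L, noiseSd = 0.0025,
                          artifactKinds = "fringe", artifactRate = 0.04),
        E = DeviceProfile("E", 1300, 2500, nChannels = 120L, noiseSd = 0.0035,
                          artifactRate = 0),
        F = DeviceProfile("F", 1350, 1650, nChannels = 60L, noiseSd = 0.0045,
                          artifactKinds = "step_fixed", artifactRate = 0.15),
        G = DeviceProfile("G", 1550, 1950, nChannels = 80L, noiseSd = 0.0045,
                          artifactKinds = "step_random", artifactRate = 0.15),
        H = DeviceProfile("H", 1750, 2150, nChannels = 80L, noiseSd = 0.0045,
                          artifactKinds = "step_random", artifactRate = 0.15)
    )
}
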