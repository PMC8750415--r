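## Pure-component absorbance curves as sums of Gaussian bands. Band positions
## are loosely anchored to the NIR overtone/combination regions of the milk
## powder constituents (water ~970/1450/1940 nm, protein N-H ~1510/2050 nm,
## carbohydrate O-H/C-H ~1440/1590/2100 nm, fat C-H ~1210/1720/2310 nm);
## amplitudes are in absorbance units per g/100 g. Cornstarch deliberately
## shadows the lactose curve: both are carbohydrates, which is what makes
## starch hard to see against natural lactose variability.

.BAND_TABLE <- list(
    protein = cbind(center = c(760, 850, 910, 1020, 1130, 1180, 1510, 1570, 1690,
                               1790, 1980, 2055, 2170, 2290),
                    width  = c(45, 70, 30, 55, 25, 50, 50, 25, 55, 30, 60, 60,
                               55, 40),
                    amp    = c(0.0009, 0.0010, 0.0006, 0.0018, 0.0007, 0.0020,
                               0.0060, 0.0020, 0.0030, 0.0015, 0.0040,
                               0.0080, 0.0070, 0.0030)),
    lactose = cbind(center = c(775, 830, 950, 990, 1090, 1200, 1440, 1530, 1590,
                               1700, 1780, 2100, 2280),
                    width  = c(45, 60, 25, 45, 30, 55, 60, 25, 50, 30, 45, 70,
                               55),
                    amp    = c(0.0008, 0.0008, 0.0005, 0.0014, 0.0007, 0.0018,
                               0.0050, 0.0015, 0.0030, 0.0012, 0.0020,
                               0.0080, 0.0040)),
    fat = cbind(center = c(770, 880, 930, 1040, 1210, 1390, 1720, 1760, 2140,
                           2310),
                width  = c(35, 35, 30, 45, 40, 50, 35, 40, 45, 35),
                amp    = c(0.0006, 0.0008, 0.0020, 0.0012, 0.0040, 0.0020, 0.0060,
                           0.0040, 0.0025, 0.0070)),
    moisture = cbind(center = c(755, 840, 970, 1150, 1190, 1450, 1790, 1940,
                                2080, 2220),
                     width  = c(50, 70, 40, 30, 55, 45, 60, 55, 40, 75),
                     amp    = c(0.0020, 0.0040, 0.0085, 0.0020, 0.0040, 0.0250,
                                0.0060, 0.0320, 0.0050, 0.0080)),
    ## supplier / process latent factors of the authentic matrix: heat load
    ## (Maillard and whey denaturation markers), whey/casein balance and
    ## lactose crystallinity; amplitudes are per unit latent score
    heat = cbind(center = c(765, 870, 1000, 1110, 1240, 1420, 1560, 1740, 1920,
                            2050, 2230, 2400),
                 width  = c(35, 30, 45, 25, 50, 30, 45, 30, 50, 30, 45, 50),
                 amp    = c(0.00225, 0.003, 0.0045, 0.00225, 0.00525, 0.003, 0.005625,
                            0.003375, 0.006, 0.00375, 0.00525, 0.0045)),
    whey = cbind(center = c(745, 820, 940, 1060, 1160, 1300, 1480, 1640, 1860,
                            2010, 2120, 2340),
                 width  = c(40, 45, 25, 40, 30, 55, 30, 45, 35, 50, 30, 45),
                 amp    = c(0.0027, 0.00375, 0.00225, 0.0045, 0.002625, 0.00525, 0.003375,
                            0.004875, 0.003, 0.00525, 0.003375, 0.0045)),
    crystallinity = cbind(center = c(790, 860, 1010, 1085, 1220, 1360, 1540,
                                     1680, 1830, 1960, 2180, 2430),
                          width  = c(35, 25, 35, 25, 40, 30, 40, 25, 45, 30,
                                     40, 45),
                          amp    = c(0.00195, 0.002625, 0.00375, 0.001875, 0.0045, 0.002625,
                                     0.0045, 0.002625, 0.004875, 0.003, 0.0045,
                                     0.00375)),
    ammonium_sulfate = cbind(center = c(900, 1000, 1270, 1500, 2050, 2200),
                             width  = c(55, 45, 55, 50, 65, 55),
                             amp    = c(0.0006, 0.0010, 0.0012, 0.0040,
                                        0.0060, 0.0025)),
    semicarbazide = cbind(center = c(920, 1030, 1290, 1490, 1990, 2150),
                          width  = c(50, 45, 55, 45, 55, 50),
                          amp    = c(0.0006, 0.0010, 0.0012, 0.0050, 0.0060,
                                     0.0025)),
    ## cornstarch tracks the lactose curve closely (both carbohydrates, the
    ## premise of the 90% lactose-equivalence dose basis); only a weak
    ## amylose/amylopectin signature distinguishes it, which is what makes
    ## starch hard to see against natural lactose variability
    cornstarch = cbind(center = c(778, 832, 952, 992, 1092, 1202, 1442, 1532,
                                  1592, 1702, 1782, 2102, 2282, 2030),
                       width  = c(45, 60, 25, 45, 30, 55, 60, 25, 50, 30, 45,
                                  70, 55, 60),
                       amp    = c(0.00074, 0.00074, 0.00047, 0.0013, 0.00065,
                                  0.00167, 0.00465, 0.0014, 0.00279, 0.00112,
                                  0.00186, 0.00744, 0.00372, 0.0006))
)

#' Pure-component spectra on a wavelength grid
#'
#' Builds the library of pure absorbance curves (sums of Gaussian bands) for
#' the milk-powder constituents (protein, lactose, fat, moisture) and the
#' three adulterants. The seed perturbs band centers (sd 3 nm) and amplitudes
#' (lognormal, 3 %) around the fixed base table, so different seeds give
#' slightly different but equally plausible chemistries; the perturbation does
#' not depend on the grid, so curves built on a sub-grid equal the pointwise
#' restriction of full-range curves.
#'
#' @param grid strictly increasing wavelength grid in nm.
#' @param seed integer seed.
#' @return Named list of non-negative numeric vectors (one per component),
#'   each of `length(grid)`, in absorbance units per g/100 g.
#' @examples
#' lib <- buildComponentLibrary(seq(900, 1700, by = 10), seed = 1)
#' names(lib)
#' @export
buildComponentLibrary <- function(grid, seed = 1L) {
    if (!length(grid)) stop("empty wavelength grid")
    if (is.unsorted(grid, strictly = TRUE))
        stop("grid must be strictly increasing")
    withSubstream(seed, "library", 0L, {
        lapply(.BAND_TABLE, function(tab) {
            centers <- tab[, "center"] + rnorm(nrow(tab), 0, 3)
            amps <- tab[, "amp"] * rlnorm(nrow(tab), 0, 0.03)
            curve <- numeric(length(grid))
            for (b in seq_len(nrow(tab)))
                curve <- curve + gaussianBand(grid, centers[b],
                                              tab[b, "width"], amps[b])
            curve
        })
    })
}
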