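## Dose arithmetic: fraud levels are expressed as a percentage of the matrix
## basis (total nitrogen for N-rich adulterants, lactose for cornstarch) and
## converted to a mass dose in g/100 g of powder.

## nitrogen mass fractions from the chemical formulas
##   ammonium sulfate (NH4)2SO4: 2 x 14.007 / 132.14
##   semicarbazide hydrochloride CH5N3O.HCl: 3 x 14.007 / 111.53
.N_MASS_FRACTION <- c(
    ammonium_sulfate = 2 * 14.007 / 132.14,
    semicarbazide = 3 * 14.007 / 111.53
)

#' Default skimmed-milk-powder composition
#'
#' Nominal bulk composition of the authentic matrix used for dose arithmetic
#' and spectra simulation. Total nitrogen is 5.28 g/100 g (protein 33.7 g/100 g
#' at the milk conversion factor 6.38) and lactose 52 g/100 g.
#'
#' @return Named list with `totalN` and `lactose`, both in g/100 g.
#' @examples
#' defaultComposition()
#' @export
defaultComposition <- function() {
    list(totalN = 5.28, lactose = 52)
}

#' Convert a fraud level to an adulterant dose
#'
#' For the nitrogen-rich adulterants (ammonium sulfate, semicarbazide) the
#' fraud level is a percentage of the matrix total nitrogen contributed
#' fraudulently, so the dose is
#' `fraudPct/100 * totalN / nitrogenMassFraction(adulterant)`. For cornstarch
#' the level is expressed on the lactose basis with a configurable
#' carbohydrate-equivalence factor (default 0.9, i.e. 90 % of the starch mass
#' counts against lactose): `fraudPct/100 * lactose / starchFactor`.
#'
#' @param adulterant one of `"ammonium_sulfate"`, `"semicarbazide"`,
#'   `"cornstarch"`.
#' @param fraudPct fraud level in percent (>= 0), vectorised.
#' @param composition list with `totalN` and `lactose` in g/100 g, see
#'   [defaultComposition()].
#' @param starchFactor lactose-equivalence factor for cornstarch.
#' @return Dose in g adulterant / 100 g powder.
#' @examples
#' doseForFraudLevel("ammonium_sulfate", 5)      # ~1.245 g/100 g
#' doseForFraudLevel("ammonium_sulfate", 3.29)   # ~0.82 g/100 g
#' @seealso [fraudPctConversion()] for the inverse.
#' @export
doseForFraudLevel <- function(adulterant, fraudPct,
                              composition = defaultComposition(),
                              starchFactor = 0.9) {
    if (any(fraudPct < 0)) stop("fraudPct must be >= 0")
    adulterant <- match.arg(adulterant, .ADULTERANTS)
    if (adulterant == "cornstarch")
        fraudPct / 100 * composition$lactose / starchFactor
    else
        fraudPct / 100 * composition$totalN / .N_MASS_FRACTION[[adulterant]]
}

#' Convert an adulterant dose back to a fraud level
#'
#' Inverse of [doseForFraudLevel()]: expresses a mass dose (g/100 g) as the
#' percentage of the matrix basis (total nitrogen or lactose) it represents.
#'
#' @inheritParams doseForFraudLevel
#' @param doseGPer100g dose in g adulterant / 100 g powder.
#' @return Fraud level in percent.
#' @examples
#' fraudPctConversion(0.82, "ammonium_sulfate")  # ~3.29 % N-fraud
#' @export
fraudPctConversion <- function(doseGPer100g, adulterant,
                               composition = defaultComposition(),
                               starchFactor = 0.9) {
    if (any(doseGPer100g < 0)) stop("dose must be >= 0")
    adulterant <- match.arg(adulterant, .ADULTERANTS)
    if (adulterant == "cornstarch")
        100 * doseGPer100g * starchFactor / composition$lactose
    else
        100 * doseGPer100g * .N_MASS_FRACTION[[adulterant]] / composition$totalN
}

#' Nitrogen mass fraction of an adulterant
#'
#' @param adulterant `"ammonium_sulfate"` or `"semicarbazide"`.
#' @return Mass fraction of nitrogen computed from the chemical formula.
#' @examples
#' nitrogenMassFraction("ammonium_sulfate")  # ~0.2120
#' @export
nitrogenMassFraction <- function(adulterant) {
    adulterant <- match.arg(adulterant, names(.N_MASS_FRACTION))
    .N_MASS_FRACTION[[adulterant]]
}

#' Total solids of the wet-blend reconstitution recipe
#'
#' The wet-blending protocol reconstitutes `powderG` grams of powder in
#' `waterMl` mL of water before re-spray-drying; the total-solids content is
#' `100 * powderG / (powderG + waterMl)` (water density 1 g/mL). The default
#' recipe (30 g in 45 mL) gives 40 %.
#'
#' @param powderG powder mass in g.
#' @param waterMl water volume in mL.
#' @return Total solids in percent.
#' @examples
#' wetBlendTotalSolids()  # 40
#' @export
wetBlendTotalSolids <- function(powderG = 30, waterMl = 45) {
    if (powderG <= 0 || waterMl < 0) stop("invalid recipe")
    100 * powderG / (powderG + waterMl)
}
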