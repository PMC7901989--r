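#' The acetogenic electron ledger
#'
#' Builds the validated [ElectronLedger-class] holding the three reactions
#' of acetogenic ethanol conversion:
#' \itemize{
#'   \item ethanol oxidation: 2 EtOH + 2 H2O -> 2 acetate + 4 H2
#'   \item CO2 reduction:     4 H2 + 2 CO2 -> acetate + 2 H2O
#'   \item overall:           2 EtOH + 2 CO2 -> 3 acetate
#' }
#' together with the electron-equivalent coefficients used throughout the
#' diversion accounting (4 e-/mol ethanol oxidised, 8 e-/mol acetate
#' synthesised from CO2, 2 e-/mol H2, 1 e-/mol Fe(III) reduced). Validity
#' checks element balance of each reaction and that the overall reaction is
#' the species-wise sum of the two half reactions.
#'
#' @return an [ElectronLedger-class].
#' @examples
#' electronLedger()
#' @export
electronLedger <- function() {
  new("ElectronLedger",
      reactions = list(
        ethanol_oxidation = c(ethanol = -2, water = -2, acetate = 2, H2 = 4),
        co2_reduction     = c(H2 = -4, CO2 = -2, acetate = 1, water = 2),
        overall           = c(ethanol = -2, CO2 = -2, acetate = 3)
      ),
      electron_equivalents = c(ethanol_ox = 4, acetate_synth = 8,
                               H2 = 2, Fe = 1))
}

#' Theoretical acetate yield from consumed ethanol
#'
#' Under the overall acetogenic reaction (2 ethanol + 2 CO2 -> 3 acetate),
#' each mole of ethanol yields 1.5 moles of acetate.
#'
#' @param ethanol_consumed amount of ethanol consumed (any amount unit).
#' @return 1.5 x \code{ethanol_consumed}, same unit.
#' @examples
#' theoreticalAcetate(0.4)  # 0.6 mmol from 20 mM ethanol in 20 mL
#' @export
theoreticalAcetate <- function(ethanol_consumed) {
  if (any(ethanol_consumed < 0)) stop("ethanol_consumed must be >= 0")
  coef <- electronLedger()@reactions$overall
  (coef[["acetate"]] / -coef[["ethanol"]]) * ethanol_consumed
}

#' Electron equivalents carried, released or sunk by a species
#'
#' Ethanol oxidation releases 4 e-/mol; acetate synthesis from CO2 sinks
#' 8 e-/mol (4 H2 per acetate); H2 carries 2 e-/mol; Fe(III) -> Fe(II)
#' sinks 1 e-/mol. The unit prefix of \code{amount} is preserved.
#'
#' @param species one of \code{"ethanol_ox"}, \code{"acetate_synth"},
#'   \code{"H2"}, \code{"Fe"}.
#' @param amount amount of the species (umol or mmol), >= 0.
#' @return electron equivalents, same unit prefix as \code{amount}.
#' @examples
#' electronEquivalents("acetate_synth", 31)  # 248 umol e-
#' electronEquivalents("H2", 3.2)            # 6.4 mmol e-
#' @export
electronEquivalents <- function(species, amount) {
  ee <- electronLedger()@electron_equivalents
  species <- match.arg(species, names(ee))
  if (any(amount < 0)) stop("amount must be >= 0")
  unname(ee[species]) * amount
}

#' Electrons diverted from acetate synthesis
#'
#' Converts the acetate deficit of an iron-amended culture relative to its
#' iron-free control into diverted electron equivalents (8 e- per acetate
#' not synthesised from CO2). Replicate noise can make a small deficit
#' negative; such deficits are clamped to zero and flagged rather than
#' raised, since observed deficits are only a few percent of the control
#' acetate.
#'
#' @param control_acetate acetate in the control culture (umol).
#' @param treatment_acetate acetate in the iron-amended culture (umol).
#' @return electron equivalents diverted (umol) with attribute
#'   \code{"flagged"} set to \code{TRUE} when the raw deficit was negative.
#' @examples
#' acetateDeficitElectrons(631, 600)  # 248 umol e-
#' @export
acetateDeficitElectrons <- function(control_acetate, treatment_acetate) {
  if (any(control_acetate < 0) || any(treatment_acetate < 0))
    stop("acetate amounts must be >= 0")
  deficit <- control_acetate - treatment_acetate
  flagged <- deficit < 0
  if (any(flagged))
    warning("negative acetate deficit clamped to zero (treatment > control)")
  out <- electronEquivalents("acetate_synth", pmax(deficit, 0))
  attr(out, "flagged") <- flagged
  out
}

#' Fraction of diverted electrons recovered as Fe(II)
#'
#' @param fe2_electrons electron equivalents appearing as Fe(II) (umol;
#'   numerically equal to umol Fe(II) since Fe(III) -> Fe(II) is a
#'   one-electron reduction).
#' @param diverted_electrons electron equivalents diverted from acetate
#'   synthesis (umol), > 0.
#' @return the exact quotient \code{fe2_electrons / diverted_electrons}.
#' @examples
#' diversionEfficiency(58, 248)  # 0.2339...
#' @export
diversionEfficiency <- function(fe2_electrons, diverted_electrons) {
  if (any(fe2_electrons < 0)) stop("fe2_electrons must be >= 0")
  if (any(diverted_electrons <= 0))
    stop("diverted_electrons must be > 0 (ratio undefined otherwise)")
  fe2_electrons / diverted_electrons
}

#' Moles of gas in a culture-bottle headspace
#'
#' Ideal-gas amount n = PV/RT with R = 8.314 J/(mol K); with pressure in
#' kPa and volume in mL the result is directly in mmol.
#'
#' @param partial_pressure_kPa partial pressure (kPa), > 0.
#' @param headspace_volume_mL headspace volume (mL), > 0.
#' @param temperature_K temperature (K), > 0; cultivation default 303.15 K
#'   (30 degrees C).
#' @return amount in mmol.
#' @examples
#' headspaceGasMoles(160, 48)  # H2 at 80% of 200 kPa in a 48 mL headspace
#' @export
headspaceGasMoles <- function(partial_pressure_kPa, headspace_volume_mL,
                              temperature_K = 303.15) {
  if (any(partial_pressure_kPa <= 0) || any(headspace_volume_mL <= 0) ||
      any(temperature_K <= 0))
    stop("pressure, volume and temperature must all be > 0")
  partial_pressure_kPa * headspace_volume_mL / (8.314 * temperature_K)
}

#' Construct a MineralSpec
#'
#' @param name mineral name.
#' @param formula chemical formula.
#' @param fe3_per_unit Fe(III) atoms per formula unit.
#' @param fe2_per_unit Fe(II) atoms per formula unit.
#' @return a [MineralSpec-class].
#' @export
mineralSpec <- function(name, formula, fe3_per_unit, fe2_per_unit = 0) {
  new("MineralSpec", name = as.character(name), formula = as.character(formula),
      fe3_per_unit = as.numeric(fe3_per_unit),
      fe2_per_unit = as.numeric(fe2_per_unit))
}

#' Built-in iron mineral table
#'
#' Reads the editable mineral config shipped with the package (HFO,
#' goethite, hematite, magnetite, Fe-NTA with their Fe(III)/Fe(II) counts
#' per formula unit).
#'
#' @param path optional path to an alternative config (CSV with columns
#'   \code{name,formula,fe3_per_unit,fe2_per_unit}).
#' @return named list of [MineralSpec-class] objects.
#' @examples
#' mineralTable()$hematite
#' @export
mineralTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "minerals.csv", package = "ferracet",
                        mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    mineralSpec(df$name[i], df$formula[i], df$fe3_per_unit[i],
                df$fe2_per_unit[i]))
  names(out) <- df$name
  out
}

#' Mineral loading equivalent to a target Fe(III) concentration
#'
#' Crystalline-oxide media are loaded to carry the same number of Fe(III)
#' atoms as the 9 mM HFO medium: e.g. hematite (Fe2O3, 2 Fe(III)/unit)
#' requires 4.5 mmol/L and goethite (FeO(OH), 1 Fe(III)/unit) 9 mmol/L.
#'
#' @param mineral a [MineralSpec-class] or a name resolvable by
#'   [mineralTable()].
#' @param target_fe3_mM target Fe(III) concentration (mM), >= 0.
#' @return mineral loading in mmol/L.
#' @examples
#' mineralLoadingForFe("hematite", 9)  # 4.5
#' @export
mineralLoadingForFe <- function(mineral, target_fe3_mM) {
  if (is.character(mineral)) {
    tab <- mineralTable()
    if (!mineral %in% names(tab)) stop(sprintf("unknown mineral '%s'", mineral))
    mineral <- tab[[mineral]]
  }
  stopifnot(is(mineral, "MineralSpec"))
  if (any(target_fe3_mM < 0)) stop("target_fe3_mM must be >= 0")
  if (mineral@fe3_per_unit == 0)
    stop(sprintf("mineral '%s' contains no Fe(III)", mineral@name))
  target_fe3_mM / mineral@fe3_per_unit
}
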