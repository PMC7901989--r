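#' @import methods
NULL

## Tolerance (mM) used by validity checks on iron measurements; below the
## replicate SD of the ferrozine assay in typical triplicate cultures.
.CONC_TOL <- 0.05

.CONDITIONS <- c("organotrophic", "lithotrophic", "dialysis", "mineral-variant")
.MINERALS   <- c("HFO", "goethite", "hematite", "Fe-NTA", "none")

#' CultureSeries: one replicate's culture time series
#'
#' Container for the timestamped measurements of a single culture replicate:
#' cell density, ethanol, acetate and Fe(II) (total and soluble), together
#' with condition metadata (species, growth condition, iron mineral) and the
#' initial Fe(III) loading.
#'
#' Optional channels (\code{ethanol_mM}, \code{fe2_soluble_mM}) may be empty
#' (length zero) or carry \code{NA} at unmeasured timepoints; missing values
#' are never encoded as zeros.
#'
#' @slot species_label character(1), e.g. \code{"GT1"}.
#' @slot condition one of \code{"organotrophic"}, \code{"lithotrophic"},
#'   \code{"dialysis"}, \code{"mineral-variant"}.
#' @slot mineral one of \code{"HFO"}, \code{"goethite"}, \code{"hematite"},
#'   \code{"Fe-NTA"}, \code{"none"}.
#' @slot replicate_id character(1).
#' @slot time_days strictly increasing non-negative numeric vector (days).
#' @slot cell_density cells/mL at each timepoint (may be empty).
#' @slot ethanol_mM optional ethanol concentration (mM).
#' @slot acetate_mM acetate concentration (mM).
#' @slot fe2_total_mM total Fe(II) (mM).
#' @slot fe2_soluble_mM optional soluble Fe(II) (mM).
#' @slot fe3_initial_mM initial Fe(III) loading (mM), >= 0.
#' @slot culture_volume_mL culture liquid volume (mL), > 0; 20 mL for bottle
#'   cultures, 120 mL for the dialysis set-up.
#'
#' @seealso [CultureSeries()], [readCultureTable()]
#' @exportClass CultureSeries
setClass("CultureSeries",
  representation(
    species_label     = "character",
    condition         = "character",
    mineral           = "character",
    replicate_id      = "character",
    time_days         = "numeric",
    cell_density      = "numeric",
    ethanol_mM        = "numeric",
    acetate_mM        = "numeric",
    fe2_total_mM      = "numeric",
    fe2_soluble_mM    = "numeric",
    fe3_initial_mM    = "numeric",
    culture_volume_mL = "numeric"
  ),
  prototype(
    species_label = "unknown", condition = "organotrophic", mineral = "HFO",
    replicate_id = "r1", fe3_initial_mM = 9, culture_volume_mL = 20
  )
)

setValidity("CultureSeries", function(object) {
  msgs <- character()
  t <- object@time_days
  n <- length(t)
  if (n == 0L) msgs <- c(msgs, "time_days must be non-empty")
  if (any(t < 0)) msgs <- c(msgs, "time_days must be non-negative")
  if (n > 1L && any(diff(t) <= 0))
    msgs <- c(msgs, "time_days must be strictly increasing")
  if (!object@condition %in% .CONDITIONS)
    msgs <- c(msgs, sprintf("condition must be one of: %s",
                            paste(.CONDITIONS, collapse = ", ")))
  if (!object@mineral %in% .MINERALS)
    msgs <- c(msgs, sprintf("mineral must be one of: %s",
                            paste(.MINERALS, collapse = ", ")))
  for (sl in c("cell_density", "ethanol_mM", "acetate_mM",
               "fe2_total_mM", "fe2_soluble_mM")) {
    v <- slot(object, sl)
    if (length(v) != 0L && length(v) != n)
      msgs <- c(msgs, sprintf("%s must have length 0 or length(time_days)", sl))
  }
  if (length(object@fe2_soluble_mM) == length(object@fe2_total_mM) &&
      length(object@fe2_total_mM) > 0L) {
    bad <- which(object@fe2_soluble_mM > object@fe2_total_mM + .CONC_TOL)
    if (length(bad))
      msgs <- c(msgs, sprintf(
        "fe2_soluble_mM exceeds fe2_total_mM beyond tolerance at timepoint(s) %s",
        paste(bad, collapse = ",")))
  }
  if (length(object@fe3_initial_mM) != 1L || object@fe3_initial_mM < 0)
    msgs <- c(msgs, "fe3_initial_mM must be a single value >= 0")
  else if (length(object@fe2_total_mM) &&
           any(object@fe2_total_mM > object@fe3_initial_mM + .CONC_TOL,
               na.rm = TRUE))
    msgs <- c(msgs, "fe2_total_mM exceeds fe3_initial_mM beyond tolerance")
  if (length(object@culture_volume_mL) != 1L || object@culture_volume_mL <= 0)
    msgs <- c(msgs, "culture_volume_mL must be a single value > 0")
  if (length(msgs)) msgs else TRUE
})

#' ElectronLedger: acetogenic reactions and electron equivalents
#'
#' The three acetogenic reactions (ethanol oxidation to acetate, CO2
#' reduction to acetate, and their sum, the overall conversion of ethanol
#' plus CO2 to acetate) stored as stoichiometric coefficient vectors over
#' the chemical species involved, plus the electron-equivalent coefficients
#' used for diversion accounting: ethanol oxidation releases 4 e-/mol,
#' acetate synthesis from CO2 sinks 8 e-/mol, H2 carries 2 e-/mol and
#' Fe(III) -> Fe(II) sinks 1 e-/mol.
#'
#' Validity confirms that every reaction is element-balanced and that the
#' overall reaction equals the sum of the two half reactions
#' species-by-species.
#'
#' @slot reactions named list of named numeric coefficient vectors
#'   (negative = consumed, positive = produced).
#' @slot electron_equivalents named numeric vector with entries
#'   \code{ethanol_ox}, \code{acetate_synth}, \code{H2}, \code{Fe}.
#'
#' @seealso [electronLedger()], [electronEquivalents()]
#' @exportClass ElectronLedger
setClass("ElectronLedger",
  representation(reactions = "list", electron_equivalents = "numeric"))

## Elemental composition of the ledger species (C, H, O).
.SPECIES_ELEMENTS <- list(
  ethanol = c(C = 2, H = 6, O = 1),
  water   = c(C = 0, H = 2, O = 1),
  acetate = c(C = 2, H = 4, O = 2),
  H2      = c(C = 0, H = 2, O = 0),
  CO2     = c(C = 1, H = 0, O = 2)
)

.reactionElementBalance <- function(coef) {
  bal <- c(C = 0, H = 0, O = 0)
  for (sp in names(coef))
    bal <- bal + coef[[sp]] * .SPECIES_ELEMENTS[[sp]]
  bal
}

setValidity("ElectronLedger", function(object) {
  msgs <- character()
  need <- c("ethanol_oxidation", "co2_reduction", "overall")
  if (!all(need %in% names(object@reactions)))
    return("reactions must contain ethanol_oxidation, co2_reduction, overall")
  for (rn in need) {
    coef <- object@reactions[[rn]]
    if (!all(names(coef) %in% names(.SPECIES_ELEMENTS)))
      return(sprintf("unknown species in reaction '%s'", rn))
    if (any(abs(.reactionElementBalance(coef)) > 1e-12))
      msgs <- c(msgs, sprintf("reaction '%s' is not element-balanced", rn))
  }
  sp <- names(.SPECIES_ELEMENTS)
  pad <- function(coef) {
    out <- setNames(numeric(length(sp)), sp); out[names(coef)] <- coef; out
  }
  if (any(abs(pad(object@reactions$overall) -
              (pad(object@reactions$ethanol_oxidation) +
               pad(object@reactions$co2_reduction))) > 1e-12))
    msgs <- c(msgs, "overall reaction must equal the sum of the half reactions")
  ee <- object@electron_equivalents
  if (!all(c("ethanol_ox", "acetate_synth", "H2", "Fe") %in% names(ee)))
    msgs <- c(msgs, "electron_equivalents must name ethanol_ox, acetate_synth, H2, Fe")
  if (length(msgs)) msgs else TRUE
})

#' MineralSpec: iron content of an Fe mineral formula unit
#'
#' @slot name character(1), e.g. \code{"hematite"}.
#' @slot formula character(1) chemical formula, e.g. \code{"Fe2O3"}.
#' @slot fe3_per_unit integer count of Fe(III) atoms per formula unit.
#' @slot fe2_per_unit integer count of Fe(II) atoms per formula unit.
#'
#' @seealso [mineralSpec()], [mineralTable()], [mineralLoadingForFe()]
#' @exportClass MineralSpec
setClass("MineralSpec",
  representation(name = "character", formula = "character",
                 fe3_per_unit = "numeric", fe2_per_unit = "numeric"))

setValidity("MineralSpec", function(object) {
  msgs <- character()
  for (sl in c("fe3_per_unit", "fe2_per_unit")) {
    v <- slot(object, sl)
    if (length(v) != 1L || v < 0 || v != round(v))
      msgs <- c(msgs, sprintf("%s must be a single non-negative integer", sl))
  }
  if (length(msgs)) msgs else TRUE
})

#' RateEstimate: fitted exponential-phase Fe(II) production rate
#'
#' Result of an ordinary least-squares fit of total Fe(II) (mM) against time
#' (days) restricted to a window of observed timepoints.
#'
#' @slot slope fitted slope, mM/day.
#' @slot intercept fitted intercept, mM.
#' @slot window numeric(2): (t_start, t_end) in days; both are observed
#'   timepoints of the series.
#' @slot n_points number of timepoints in the window (>= 3).
#' @slot r_squared coefficient of determination (\code{NA} when the response
#'   is constant).
#' @slot slope_stderr standard error of the slope, mM/day.
#'
#' @seealso [fe2ProductionRate()], [selectExponentialWindow()]
#' @exportClass RateEstimate
setClass("RateEstimate",
  representation(slope = "numeric", intercept = "numeric", window = "numeric",
                 n_points = "integer", r_squared = "numeric",
                 slope_stderr = "numeric"))

setValidity("RateEstimate", function(object) {
  msgs <- character()
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msgs <- c(msgs, "window must be (t_start, t_end) with t_start < t_end")
  if (object@n_points < 3L)
    msgs <- c(msgs, "n_points must be >= 3")
  r2 <- object@r_squared
  if (!is.na(r2) && (r2 < -1e-9 || r2 > 1 + 1e-9))
    msgs <- c(msgs, "r_squared must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' GroupComparison: one-way ANOVA plus Tukey HSD pairwise table
#'
#' @slot group_labels character vector of group names (k groups).
#' @slot group_values named list of numeric replicate values per group.
#' @slot f_statistic ANOVA F.
#' @slot anova_p ANOVA p-value.
#' @slot pairwise data.frame with one row per unordered pair (choose(k, 2)
#'   rows): \code{pair}, \code{diff}, \code{q}, \code{p_adj}, \code{stars}.
#'   Stars follow the convention \code{***} p < 0.001, \code{**} p < 0.01,
#'   \code{*} p < 0.05.
#'
#' @seealso [tukeyHsd()], [oneWayAnova()]
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(group_labels = "character", group_values = "list",
                 f_statistic = "numeric", anova_p = "numeric",
                 pairwise = "data.frame"))

setValidity("GroupComparison", function(object) {
  k <- length(object@group_labels)
  if (nrow(object@pairwise) != choose(k, 2))
    return("pairwise table must have choose(k, 2) rows")
  TRUE
})

#' AssemblyStats: contig-level summary of a nucleotide assembly
#'
#' @slot n_contigs number of contigs.
#' @slot total_length total assembly length (bp).
#' @slot gc_percent GC content, percent of unambiguous (A/C/G/T) bases.
#' @slot n50 N50 (bp): the contig length at which, scanning contigs sorted by
#'   decreasing length, the cumulative length first reaches half the total.
#'
#' @seealso [assemblyStats()]
#' @exportClass AssemblyStats
setClass("AssemblyStats",
  representation(n_contigs = "integer", total_length = "numeric",
                 gc_percent = "numeric", n50 = "numeric"))

setValidity("AssemblyStats", function(object) {
  msgs <- character()
  if (object@gc_percent < 0 || object@gc_percent > 100)
    msgs <- c(msgs, "gc_percent must lie in [0, 100]")
  if (object@n_contigs < 1L)
    msgs <- c(msgs, "n_contigs must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCultureConfig: parameters of the culture simulator
#'
#' Describes one simulated culture condition: logistic growth from the
#' standard inoculum, substrate (ethanol or H2/CO2) consumption, acetate
#' production by the acetogenic stoichiometry with a fraction \code{f_div}
#' of donor electrons diverted away from acetate synthesis, a fraction
#' \code{f_fe} of the diverted electrons captured as Fe(II), and Gaussian
#' measurement noise.
#'
#' @slot preset character(1) preset name (or \code{"custom"}).
#' @slot species_label character(1).
#' @slot condition growth condition label.
#' @slot n0 initial cell density, cells/mL.
#' @slot capacity carrying capacity, cells/mL.
#' @slot mu specific growth rate, 1/day.
#' @slot substrate \code{"ethanol"} or \code{"H2"}.
#' @slot substrate_mmol total donor available, mmol per culture (0.4 mmol for
#'   20 mM ethanol in 20 mL; 3.2 mmol H2 per bottle).
#' @slot fe3_initial_mM initial Fe(III), mM.
#' @slot f_div fraction of donor electrons diverted from acetate synthesis.
#' @slot f_fe fraction of diverted electrons recovered as Fe(II).
#' @slot fe2_rate_mM_day target exponential-phase Fe(II) production rate.
#' @slot t_active_days duration of active substrate consumption when no
#'   Fe(II) ramp defines it (used when \code{f_div} or \code{f_fe} is 0).
#' @slot noise_sd Gaussian measurement noise SD on concentrations, mM.
#' @slot sampling_days observation times, days.
#' @slot replicates number of replicate cultures.
#' @slot volume_mL culture volume, mL.
#'
#' @seealso [cultureConfig()], [generateCulture()]
#' @exportClass SyntheticCultureConfig
setClass("SyntheticCultureConfig",
  representation(
    preset = "character", species_label = "character", condition = "character",
    n0 = "numeric", capacity = "numeric", mu = "numeric",
    substrate = "character", substrate_mmol = "numeric",
    fe3_initial_mM = "numeric", f_div = "numeric", f_fe = "numeric",
    fe2_rate_mM_day = "numeric", t_active_days = "numeric",
    noise_sd = "numeric", sampling_days = "numeric",
    replicates = "integer", volume_mL = "numeric"
  )
)

setValidity("SyntheticCultureConfig", function(object) {
  msgs <- character()
  if (object@f_div < 0 || object@f_div > 1)
    msgs <- c(msgs, "f_div must lie in [0, 1]")
  if (object@f_fe < 0 || object@f_fe > 1)
    msgs <- c(msgs, "f_fe must lie in [0, 1]")
  if (object@noise_sd < 0) msgs <- c(msgs, "noise_sd must be >= 0")
  if (!object@substrate %in% c("ethanol", "H2"))
    msgs <- c(msgs, "substrate must be 'ethanol' or 'H2'")
  if (object@n0 <= 0 || object@capacity <= object@n0)
    msgs <- c(msgs, "need 0 < n0 < capacity")
  if (object@volume_mL <= 0) msgs <- c(msgs, "volume_mL must be > 0")
  if (object@replicates < 1L) msgs <- c(msgs, "replicates must be >= 1")
  if (length(msgs)) msgs else TRUE
})
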