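## Run code with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, code) {
  force(seed)  # must be drawn before the caller's RNG state is saved
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Electron equivalents released per mol of donor consumed.
.E_PER_DONOR <- c(ethanol = 4, H2 = 2)

## Preset table. f_fe is the Fe(II) capture efficiency observed in the
## GT1 ethanol culture (58 umol Fe(II) electrons out of 248 umol diverted);
## f_div is solved per preset so that f_fe * f_div * (total donor electrons)
## / volume equals the target stationary Fe(II) concentration. Rates and
## plateaus for the two strongest reducers are the measured values; the two
## weaker species use values chosen once inside the measured
## fraction-reduced ranges (13-33% organotrophic, 5-22% lithotrophic).
.presetRow <- function(species, condition, substrate, substrate_mmol,
                       rate, final_mM, volume, fe3 = 9, mu = 1.0,
                       capacity = 2e8) {
  e_total_umol <- .E_PER_DONOR[[substrate]] * substrate_mmol * 1000
  f_fe <- 58 / 248
  fe2_umol <- final_mM * volume
  f_div <- fe2_umol / (f_fe * e_total_umol)
  list(species = species, condition = condition, substrate = substrate,
       substrate_mmol = substrate_mmol, rate = rate, volume = volume,
       fe3 = fe3, mu = mu, capacity = capacity, f_div = f_div, f_fe = f_fe)
}

.PRESETS <- list(
  "gt1-organo"         = .presetRow("GT1", "organotrophic", "ethanol", 0.4, 0.47, 2.9, 20),
  "sphaeroides-organo" = .presetRow("S.sphaeroides", "organotrophic", "ethanol", 0.4, 0.39, 2.9, 20),
  "ovata-organo"       = .presetRow("S.ovata", "organotrophic", "ethanol", 0.4, 0.30, 1.8, 20),
  "woodii-organo"      = .presetRow("A.woodii", "organotrophic", "ethanol", 0.4, 0.15, 1.2, 20),
  "gt1-litho"          = .presetRow("GT1", "lithotrophic", "H2", 3.2, 0.24, 1.9, 20, mu = 0.8, capacity = 1e8),
  "sphaeroides-litho"  = .presetRow("S.sphaeroides", "lithotrophic", "H2", 3.2, 0.23, 1.9, 20, mu = 0.8, capacity = 1e8),
  "ovata-litho"        = .presetRow("S.ovata", "lithotrophic", "H2", 3.2, 0.13, 1.0, 20, mu = 0.8, capacity = 1e8),
  "woodii-litho"       = .presetRow("A.woodii", "lithotrophic", "H2", 3.2, 0.07, 0.5, 20, mu = 0.8, capacity = 1e8),
  ## dialysis: sixfold medium volume, Fe(II) plateau at 0.2% of the Fe(III)
  ## input (mid-range of the observed 0.06-0.3%).
  "gt1-dialysis"       = .presetRow("GT1", "dialysis", "ethanol", 2.4, 0.003, 0.018, 120)
)

#' Available synthetic-culture presets
#'
#' @return character vector of preset names accepted by [cultureConfig()].
#' @export
listPresets <- function() names(.PRESETS)

#' Build a synthetic-culture configuration
#'
#' Presets encode the study conditions: inoculum 1e6 cells/mL, 9 mM
#' Fe(III) as HFO, ethanol (20 mM in 20 mL; 0.4 mmol) or H2 (3.2 mmol per
#' bottle) as donor, triplicates sampled every 2 days for 14 days, and the
#' per-species Fe(II) production rate and stationary plateau. The electron
#' bookkeeping fractions \code{f_div} (donor electrons diverted from
#' acetate synthesis) and \code{f_fe} (diverted electrons captured as
#' Fe(II)) are solved algebraically from the plateau and the donor
#' electron total, anchored to the GT1 ethanol culture budget
#' (248 umol diverted, 58 umol recovered as Fe(II)).
#'
#' @param preset a name from [listPresets()], or \code{NULL} for a fully
#'   custom configuration.
#' @param noise_sd Gaussian measurement noise SD on concentrations (mM);
#'   default 0.1, matching the printed replicate error bars. Set 0 for
#'   noiseless runs.
#' @param replicates replicate cultures (default 3).
#' @param sampling_days observation times (default days 0,2,...,14).
#' @param species_label,condition,substrate,substrate_mmol,fe3_initial_mM
#'   custom-configuration fields (ignored when a preset supplies them).
#' @param f_div,f_fe electron diversion and capture fractions in [0,1].
#' @param fe2_rate_mM_day exponential-phase Fe(II) production rate.
#' @param t_active_days active substrate-consumption window used when the
#'   Fe(II) ramp does not define one (i.e. \code{f_div * f_fe == 0}).
#' @param n0,capacity,mu logistic growth parameters (cells/mL, cells/mL,
#'   1/day).
#' @param volume_mL culture volume.
#' @return a [SyntheticCultureConfig-class].
#' @examples
#' cultureConfig("gt1-organo", noise_sd = 0)
#' @export
cultureConfig <- function(preset = NULL, noise_sd = 0.1, replicates = 3,
                          sampling_days = seq(0, 14, by = 2),
                          species_label = "custom",
                          condition = "organotrophic",
                          substrate = "ethanol", substrate_mmol = 0.4,
                          fe3_initial_mM = 9, f_div = 0, f_fe = 58 / 248,
                          fe2_rate_mM_day = 0, t_active_days = 6,
                          n0 = 1e6, capacity = 2e8, mu = 1.0,
                          volume_mL = 20) {
  preset_name <- "custom"
  if (!is.null(preset)) {
    if (!preset %in% names(.PRESETS))
      stop(sprintf("unknown preset '%s'; see listPresets()", preset))
    p <- .PRESETS[[preset]]
    preset_name <- preset
    species_label <- p$species; condition <- p$condition
    substrate <- p$substrate; substrate_mmol <- p$substrate_mmol
    fe3_initial_mM <- p$fe3; f_div <- p$f_div; f_fe <- p$f_fe
    fe2_rate_mM_day <- p$rate; volume_mL <- p$volume
    n0 <- 1e6; capacity <- p$capacity; mu <- p$mu
  }
  new("SyntheticCultureConfig", preset = preset_name,
      species_label = species_label, condition = condition,
      n0 = n0, capacity = capacity, mu = mu, substrate = substrate,
      substrate_mmol = substrate_mmol, fe3_initial_mM = fe3_initial_mM,
      f_div = f_div, f_fe = f_fe, fe2_rate_mM_day = fe2_rate_mM_day,
      t_active_days = t_active_days, noise_sd = noise_sd,
      sampling_days = as.numeric(sampling_days),
      replicates = as.integer(replicates), volume_mL = volume_mL)
}

## Noiseless expectation curves for a config; f_div_use lets the control
## share the treatment's substrate trajectory with diversion switched off.
.cultureTruth <- function(config, f_div_use = config@f_div) {
  t <- config@sampling_days
  e_per <- .E_PER_DONOR[[config@substrate]]
  e_total_umol <- e_per * config@substrate_mmol * 1000
  plateau_mM <- config@f_fe * config@f_div * e_total_umol / config@volume_mL
  t_active <- if (config@fe2_rate_mM_day > 0 && plateau_mM > 0)
    plateau_mM / config@fe2_rate_mM_day else config@t_active_days
  p <- pmin(t, t_active) / t_active
  consumed_umol <- config@substrate_mmol * 1000 * p
  e_umol <- e_per * consumed_umol
  acet_umol <- (if (config@substrate == "ethanol") consumed_umol else 0) +
    e_umol * (1 - f_div_use) / 8
  fe2_mM_raw <- config@f_fe * f_div_use * e_umol / config@volume_mL
  capped <- fe2_mM_raw > config@fe3_initial_mM
  dens <- config@capacity /
    (1 + ((config@capacity - config@n0) / config@n0) * exp(-config@mu * t))
  list(time = t, density = dens,
       substrate_mM = (config@substrate_mmol * 1000 - consumed_umol) /
         config@volume_mL,
       acetate_mM = acet_umol / config@volume_mL,
       fe2_mM = pmin(fe2_mM_raw, config@fe3_initial_mM),
       capped = any(capped), plateau_mM = plateau_mM, t_active = t_active)
}

#' Generate paired synthetic culture series
#'
#' Simulates \code{replicates} iron-amended cultures and matching iron-free
#' controls under one configuration. Cell density follows logistic growth;
#' the donor is consumed linearly over the active-growth window; acetate
#' follows the acetogenic stoichiometry with the diverted-electron fraction
#' removed (controls divert nothing, so acetate is exactly 1.5 x ethanol
#' consumed); Fe(II) accrues as \code{f_fe * f_div} of the cumulative donor
#' electrons, capped at the Fe(III) input (with a warning if the cap
#' binds). Concentration observations receive i.i.d. additive Gaussian
#' noise (left untruncated, so near-zero true values can read slightly
#' negative, as an unbiased blank-subtracted assay does); cell counts
#' receive multiplicative lognormal noise (counting error scales with the
#' count).
#'
#' @param config a [SyntheticCultureConfig-class].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with elements \code{treatment} and \code{control}, each a
#'   list of [CultureSeries-class] objects, plus \code{truth} (the
#'   noiseless expectation curves and the plateau/ramp parameters).
#' @examples
#' out <- generateCulture(cultureConfig("gt1-organo", noise_sd = 0), seed = 1)
#' fe2Total(out$treatment[[1]])
#' @export
generateCulture <- function(config, seed = 1) {
  stopifnot(is(config, "SyntheticCultureConfig"))
  validObject(config)
  truth_t <- .cultureTruth(config)
  truth_c <- .cultureTruth(config, f_div_use = 0)
  if (truth_t$capped)
    warning("configured Fe(II) production exceeds the Fe(III) input; capped")
  .withSeed(seed, {
    ## plain additive noise: an unbiased assay (signal minus blank) can read
    ## slightly negative near zero, and clamping would bias slope fits at
    ## the t = 0 boundary by sigma*phi(0) -- a few percent of the rate
    noise <- function(v) {
      if (config@noise_sd == 0) v
      else v + stats::rnorm(length(v), 0, config@noise_sd)
    }
    dens_noise <- function(v) {
      if (config@noise_sd == 0) v
      else v * exp(stats::rnorm(length(v), 0, 0.05))
    }
    soluble_fraction <- 0.7  # reductively dissolved share of Fe(II)
    mkrep <- function(r, truth, with_fe) {
      fe2 <- if (with_fe) noise(truth$fe2_mM) else rep(0, length(truth$time))
      sol <- if (with_fe) {
        pmin(noise(soluble_fraction * truth$fe2_mM), fe2)
      } else numeric(0)
      CultureSeries(
        time_days = truth$time, acetate_mM = noise(truth$acetate_mM),
        fe2_total_mM = fe2, cell_density = dens_noise(truth$density),
        ethanol_mM = if (config@substrate == "ethanol")
          noise(truth$substrate_mM) else numeric(0),
        fe2_soluble_mM = sol,
        species_label = config@species_label,
        condition = config@condition,
        mineral = if (with_fe) "HFO" else "none",
        replicate_id = sprintf("r%d", r),
        fe3_initial_mM = if (with_fe) config@fe3_initial_mM else 0,
        culture_volume_mL = config@volume_mL)
    }
    treatment <- lapply(seq_len(config@replicates), mkrep, truth = truth_t,
                        with_fe = TRUE)
    control <- lapply(seq_len(config@replicates), mkrep, truth = truth_c,
                      with_fe = FALSE)
    list(treatment = treatment, control = control,
         truth = list(treatment = truth_t, control = truth_c,
                      plateau_mM = truth_t$plateau_mM,
                      rate_mM_day = config@fe2_rate_mM_day))
  })
}
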