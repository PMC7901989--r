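#' Accessors for ferracet S4 classes
#'
#' Slot accessors for [CultureSeries-class], [RateEstimate-class] and
#' friends. Use these rather than \code{@}.
#'
#' @param x an object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases speciesLabel conditionLabel mineralLabel replicateId timeDays
#'   cellDensity ethanol acetate fe2Total fe2Soluble fe3Initial cultureVolume
#'   rateSlope rateStderr fitWindow rSquared nPoints
#' @examples
#' s <- CultureSeries(time_days = c(0, 2, 4), acetate_mM = c(0, 5, 10),
#'                    fe2_total_mM = c(0, 1, 2))
#' timeDays(s)
#' fe2Total(s)
NULL

#' @rdname accessors
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("mineralLabel", function(x) standardGeneric("mineralLabel"))
#' @rdname accessors
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))
#' @rdname accessors
#' @export
setGeneric("timeDays", function(x) standardGeneric("timeDays"))
#' @rdname accessors
#' @export
setGeneric("cellDensity", function(x) standardGeneric("cellDensity"))
#' @rdname accessors
#' @export
setGeneric("ethanol", function(x) standardGeneric("ethanol"))
#' @rdname accessors
#' @export
setGeneric("acetate", function(x) standardGeneric("acetate"))
#' @rdname accessors
#' @export
setGeneric("fe2Total", function(x) standardGeneric("fe2Total"))
#' @rdname accessors
#' @export
setGeneric("fe2Soluble", function(x) standardGeneric("fe2Soluble"))
#' @rdname accessors
#' @export
setGeneric("fe3Initial", function(x) standardGeneric("fe3Initial"))
#' @rdname accessors
#' @export
setGeneric("cultureVolume", function(x) standardGeneric("cultureVolume"))
#' @rdname accessors
#' @export
setGeneric("rateSlope", function(x) standardGeneric("rateSlope"))
#' @rdname accessors
#' @export
setGeneric("rateStderr", function(x) standardGeneric("rateStderr"))
#' @rdname accessors
#' @export
setGeneric("fitWindow", function(x) standardGeneric("fitWindow"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

setMethod("speciesLabel", "CultureSeries", function(x) x@species_label)
setMethod("conditionLabel", "CultureSeries", function(x) x@condition)
setMethod("mineralLabel", "CultureSeries", function(x) x@mineral)
setMethod("replicateId", "CultureSeries", function(x) x@replicate_id)
setMethod("timeDays", "CultureSeries", function(x) x@time_days)
setMethod("cellDensity", "CultureSeries", function(x) x@cell_density)
setMethod("ethanol", "CultureSeries", function(x) x@ethanol_mM)
setMethod("acetate", "CultureSeries", function(x) x@acetate_mM)
setMethod("fe2Total", "CultureSeries", function(x) x@fe2_total_mM)
setMethod("fe2Soluble", "CultureSeries", function(x) x@fe2_soluble_mM)
setMethod("fe3Initial", "CultureSeries", function(x) x@fe3_initial_mM)
setMethod("cultureVolume", "CultureSeries", function(x) x@culture_volume_mL)

setMethod("rateSlope", "RateEstimate", function(x) x@slope)
setMethod("rateStderr", "RateEstimate", function(x) x@slope_stderr)
setMethod("fitWindow", "RateEstimate", function(x) x@window)
setMethod("rSquared", "RateEstimate", function(x) x@r_squared)
setMethod("nPoints", "RateEstimate", function(x) x@n_points)

#' @name show-methods
#' @title Show methods for ferracet classes
#' @param object an object.
#' @return \code{invisible(NULL)}, called for its side effect.
#' @keywords internal
#' @exportMethod show
setMethod("show", "CultureSeries", function(object) {
  cat(sprintf("CultureSeries: %s / %s / mineral %s / replicate %s\n",
              object@species_label, object@condition, object@mineral,
              object@replicate_id))
  cat(sprintf("  %d timepoints over %.3g-%.3g days; Fe(III) initial %.3g mM; volume %g mL\n",
              length(object@time_days), min(object@time_days),
              max(object@time_days), object@fe3_initial_mM,
              object@culture_volume_mL))
  chans <- c(cell_density = length(object@cell_density) > 0,
             ethanol = length(object@ethanol_mM) > 0,
             acetate = length(object@acetate_mM) > 0,
             fe2_total = length(object@fe2_total_mM) > 0,
             fe2_soluble = length(object@fe2_soluble_mM) > 0)
  cat("  channels:", paste(names(chans)[chans], collapse = ", "), "\n")
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf(
    "RateEstimate: slope %.4g +/- %.3g mM/day over [%g, %g] days (n = %d, R^2 = %s)\n",
    object@slope, object@slope_stderr, object@window[1], object@window[2],
    object@n_points,
    ifelse(is.na(object@r_squared), "NA", sprintf("%.4f", object@r_squared))))
})

setMethod("show", "ElectronLedger", function(object) {
  cat("ElectronLedger with reactions:\n")
  for (rn in names(object@reactions)) {
    coef <- object@reactions[[rn]]
    lhs <- coef[coef < 0]; rhs <- coef[coef > 0]
    cat(sprintf("  %s: %s -> %s\n", rn,
                paste(sprintf("%g %s", -lhs, names(lhs)), collapse = " + "),
                paste(sprintf("%g %s", rhs, names(rhs)), collapse = " + ")))
  }
  ee <- object@electron_equivalents
  cat("  electron equivalents:",
      paste(sprintf("%s = %g", names(ee), ee), collapse = ", "), "\n")
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison: %d groups; F = %.4g, p = %.3g\n",
              length(object@group_labels), object@f_statistic, object@anova_p))
  print(object@pairwise, row.names = FALSE)
})

setMethod("show", "AssemblyStats", function(object) {
  cat(sprintf("AssemblyStats: %d contigs, %g bp, GC %.1f%%, N50 %g bp\n",
              object@n_contigs, object@total_length, object@gc_percent,
              object@n50))
})

setMethod("show", "MineralSpec", function(object) {
  cat(sprintf("MineralSpec: %s (%s), %d Fe(III) + %d Fe(II) per unit\n",
              object@name, object@formula, object@fe3_per_unit,
              object@fe2_per_unit))
})

setMethod("show", "SyntheticCultureConfig", function(object) {
  cat(sprintf("SyntheticCultureConfig '%s': %s, %s on %s\n", object@preset,
              object@species_label, object@condition, object@substrate))
  cat(sprintf("  f_div = %.4g, f_fe = %.4g, Fe(II) rate = %g mM/day, noise SD = %g mM\n",
              object@f_div, object@f_fe, object@fe2_rate_mM_day,
              object@noise_sd))
  cat(sprintf("  %d replicates, %g mL, Fe(III) %g mM, sampled at days %s\n",
              object@replicates, object@volume_mL, object@fe3_initial_mM,
              paste(object@sampling_days, collapse = ",")))
})
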