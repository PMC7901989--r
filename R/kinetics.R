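## Straight-line fit helper: returns slope, intercept, stderr, r2.
.olsLine <- function(x, y) {
  n <- length(x)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  se <- if (n > 2) sqrt(ss_res / (n - 2) / sum((x - mean(x))^2)) else NA_real_
  list(slope = slope, intercept = intercept, r_squared = r2,
       slope_stderr = se)
}

#' Select the exponential-growth window of a culture series
#'
#' The exponential phase is operationalised as the contiguous window of
#' observed timepoints, of length at least \code{min_points}, that maximises
#' the R-squared of a straight-line fit of log10(cell density) against time.
#' Candidate windows must contain the sampling interval with the fastest
#' observed specific growth (the steepest log-density step per day): the
#' exponential phase by definition includes the moment of fastest growth,
#' and without this qualification a chance-collinear window in the
#' stationary phase can displace the true exponential window on noisy
#' data. Windows whose R-squared is within \code{tie_tol} of the maximum
#' are treated as ties — at 3-8 point windows smaller differences in fit
#' quality are not statistically meaningful — broken toward the longer
#' window, then toward the earlier start.
#'
#' @param series a [CultureSeries-class] with cell densities recorded.
#' @param min_points minimum window length (default 3).
#' @param tie_tol R-squared margin treated as a tie (default 0.005).
#' @return numeric(2): (t_start, t_end), both observed timepoints.
#' @examples
#' cfg <- cultureConfig("gt1-organo", noise_sd = 0)
#' s <- generateCulture(cfg, seed = 1)$treatment[[1]]
#' selectExponentialWindow(s)
#' @export
selectExponentialWindow <- function(series, min_points = 3, tie_tol = 0.005) {
  t <- timeDays(series)
  dens <- cellDensity(series)
  if (length(dens) != length(t) || length(t) < min_points)
    stop(sprintf("need at least %d timepoints with cell density", min_points))
  if (any(dens <= 0)) stop("cell densities must be positive")
  if (length(unique(dens)) == 1L)
    stop("cell density is constant: no exponential phase")
  y <- log10(dens)
  n <- length(t)
  steps <- diff(y) / diff(t)
  peak <- which(steps >= max(steps) - 1e-9)  # interval(s) of fastest growth
  cand <- list()
  for (len in min_points:n) {
    for (start in 1:(n - len + 1)) {
      idx <- start:(start + len - 1)
      if (length(unique(y[idx])) == 1L) next
      if (!any(peak >= start & peak <= start + len - 2L)) next
      cand[[length(cand) + 1L]] <-
        c(r2 = .olsLine(t[idx], y[idx])$r_squared, len = len, start = start)
    }
  }
  if (!length(cand)) stop("no usable window found")
  cand <- do.call(rbind, cand)
  top <- cand[cand[, "r2"] >= max(cand[, "r2"]) - tie_tol, , drop = FALSE]
  top <- top[top[, "len"] == max(top[, "len"]), , drop = FALSE]
  best <- top[which.min(top[, "start"]), ]
  c(t[best[["start"]]], t[best[["start"]] + best[["len"]] - 1])
}

#' Exponential-phase Fe(II) production rate
#'
#' Ordinary least-squares slope of total Fe(II) (mM) against time (days)
#' restricted to a window of observed timepoints, with slope standard error
#' and R-squared. When no window is supplied the exponential-growth window
#' from [selectExponentialWindow()] is used.
#'
#' @param series a [CultureSeries-class].
#' @param window numeric(2) (t_start, t_end) in days, or \code{NULL} to
#'   auto-select from cell density.
#' @return a [RateEstimate-class].
#' @examples
#' s <- CultureSeries(time_days = c(0, 2, 4, 6),
#'                    acetate_mM = c(0, 5, 10, 15),
#'                    fe2_total_mM = 0.5 * c(0, 2, 4, 6))
#' fe2ProductionRate(s, window = c(0, 6))
#' @export
fe2ProductionRate <- function(series, window = NULL) {
  if (is.null(window)) window <- selectExponentialWindow(series)
  t <- timeDays(series)
  fe2 <- fe2Total(series)
  idx <- which(t >= window[1] - 1e-12 & t <= window[2] + 1e-12 & !is.na(fe2))
  if (length(idx) < 3)
    stop("window must contain at least 3 timepoints with Fe(II) recorded")
  fit <- .olsLine(t[idx], fe2[idx])
  new("RateEstimate", slope = fit$slope, intercept = fit$intercept,
      window = c(t[idx[1]], t[idx[length(idx)]]),
      n_points = length(idx), r_squared = fit$r_squared,
      slope_stderr = fit$slope_stderr)
}

#' Stationary-phase Fe(II) accumulation
#'
#' Mean of the final \code{k_last} total-Fe(II) observations, the package's
#' estimator of the stationary plateau.
#'
#' @param series a [CultureSeries-class].
#' @param k_last number of trailing observations to average (default 2).
#' @return plateau estimate (mM).
#' @export
finalAccumulation <- function(series, k_last = 2) {
  if (k_last < 1) stop("k_last must be >= 1")
  fe2 <- fe2Total(series)
  fe2 <- fe2[!is.na(fe2)]
  if (length(fe2) < k_last)
    stop(sprintf("need at least %d Fe(II) observations", k_last))
  mean(utils::tail(fe2, k_last))
}

#' Percentage of the initial Fe(III) reduced to Fe(II)
#'
#' @param fe2_final_mM final Fe(II) (mM), >= 0.
#' @param fe3_initial_mM initial Fe(III) (mM), > 0.
#' @return percent (0-100 scale; may exceed 100 only through assay error).
#' @examples
#' fractionReduced(2.9, 9)  # 32.2%
#' @export
fractionReduced <- function(fe2_final_mM, fe3_initial_mM) {
  if (any(fe3_initial_mM <= 0)) stop("fe3_initial_mM must be > 0")
  if (any(fe2_final_mM < 0)) stop("fe2_final_mM must be >= 0")
  100 * fe2_final_mM / fe3_initial_mM
}

#' Sediment-associated iron by difference
#'
#' Sediment iron is total minus soluble (supernatant) iron. Supernatant
#' occasionally exceeds total through assay noise; the difference is then
#' clamped to zero and flagged when the excess is beyond the 0.05 mM
#' tolerance.
#'
#' @param total_mM total iron (mM), >= 0.
#' @param supernatant_mM soluble iron (mM), >= 0.
#' @return sediment iron (mM) with attribute \code{"flagged"} marking
#'   over-subtractions beyond tolerance.
#' @export
partitionSediment <- function(total_mM, supernatant_mM) {
  if (any(total_mM < 0) || any(supernatant_mM < 0))
    stop("iron concentrations must be >= 0")
  out <- pmax(total_mM - supernatant_mM, 0)
  flagged <- supernatant_mM > total_mM + .CONC_TOL
  if (any(flagged))
    warning("supernatant exceeds total beyond tolerance; difference clamped to 0")
  attr(out, "flagged") <- flagged
  out
}

#' Per-series kinetics report
#'
#' Runs the full kinetics battery on each series: exponential-window rate
#' fit, stationary accumulation, percent of Fe(III) reduced, and the
#' soluble/sediment split at the final timepoint (when soluble Fe(II) was
#' measured).
#'
#' @param series list of [CultureSeries-class] objects (or a single one).
#' @param window optional fixed window applied to every series.
#' @param k_last trailing points for the plateau estimate.
#' @return data.frame with one row per series.
#' @export
kineticsReport <- function(series, window = NULL, k_last = 2) {
  if (is(series, "CultureSeries")) series <- list(series)
  rows <- lapply(series, function(s) {
    est <- fe2ProductionRate(s, window = window)
    plateau <- finalAccumulation(s, k_last = k_last)
    pct <- if (fe3Initial(s) > 0) fractionReduced(plateau, fe3Initial(s))
           else NA_real_
    sol <- fe2Soluble(s)
    sed <- if (length(sol)) {
      last <- max(which(!is.na(sol)))
      as.numeric(partitionSediment(fe2Total(s)[last], sol[last]))
    } else NA_real_
    data.frame(species = speciesLabel(s), condition = conditionLabel(s),
               mineral = mineralLabel(s), replicate = replicateId(s),
               rate_mM_day = rateSlope(est), rate_stderr = rateStderr(est),
               r_squared = rSquared(est),
               window_start = fitWindow(est)[1], window_end = fitWindow(est)[2],
               final_fe2_mM = plateau, pct_fe3_reduced = pct,
               sediment_fe2_mM = sed, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
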