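#' Construct a CultureSeries
#'
#' @param time_days strictly increasing non-negative times (days).
#' @param acetate_mM acetate per timepoint (mM).
#' @param fe2_total_mM total Fe(II) per timepoint (mM).
#' @param cell_density,ethanol_mM,fe2_soluble_mM optional channels; pass
#'   \code{numeric(0)} (default) when not measured.
#' @param species_label,condition,mineral,replicate_id metadata.
#' @param fe3_initial_mM initial Fe(III) loading (mM).
#' @param culture_volume_mL liquid volume (mL); defaults to 20 mL, or 120 mL
#'   for the dialysis condition.
#' @return a validated [CultureSeries-class].
#' @examples
#' CultureSeries(time_days = c(0, 2, 4), acetate_mM = c(0, 8, 16),
#'               fe2_total_mM = c(0, 0.9, 1.9))
#' @export
CultureSeries <- function(time_days, acetate_mM, fe2_total_mM,
                          cell_density = numeric(0), ethanol_mM = numeric(0),
                          fe2_soluble_mM = numeric(0),
                          species_label = "unknown",
                          condition = "organotrophic", mineral = "HFO",
                          replicate_id = "r1", fe3_initial_mM = 9,
                          culture_volume_mL = NULL) {
  if (is.null(culture_volume_mL))
    culture_volume_mL <- if (identical(condition, "dialysis")) 120 else 20
  new("CultureSeries",
      species_label = as.character(species_label),
      condition = as.character(condition), mineral = as.character(mineral),
      replicate_id = as.character(replicate_id),
      time_days = as.numeric(time_days),
      cell_density = as.numeric(cell_density),
      ethanol_mM = as.numeric(ethanol_mM),
      acetate_mM = as.numeric(acetate_mM),
      fe2_total_mM = as.numeric(fe2_total_mM),
      fe2_soluble_mM = as.numeric(fe2_soluble_mM),
      fe3_initial_mM = as.numeric(fe3_initial_mM),
      culture_volume_mL = as.numeric(culture_volume_mL))
}

.CULTURE_COLS <- c("species", "condition", "mineral", "replicate",
                   "time_days", "cells_per_ml", "ethanol_mM", "acetate_mM",
                   "fe2_total_mM", "fe2_soluble_mM", "fe3_initial_mM",
                   "culture_volume_mL")

.numericColumn <- function(raw, col) {
  v <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & is.na(v))
  if (length(bad))
    stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                 col, bad[1], raw[bad[1]]), call. = FALSE)
  v[!is.na(raw) & raw == ""] <- NA_real_
  v
}

#' Read culture time-series tables
#'
#' Reads a CSV/TSV of per-timepoint culture measurements (one row per
#' replicate x timepoint) and splits it into one [CultureSeries-class] per
#' (species, condition, mineral, replicate) group, rows sorted by time.
#' Units are taken at face value: days, cells/mL, mM.
#'
#' The expected header is
#' \code{species,condition,mineral,replicate,time_days,cells_per_ml,ethanol_mM,acetate_mM,fe2_total_mM,fe2_soluble_mM}
#' (optionally plus \code{fe3_initial_mM} and \code{culture_volume_mL});
#' lines starting with \code{#} are comments. Missing optional measurements
#' are empty cells, read as \code{NA} — never zeros.
#'
#' @param path file path.
#' @param sep field separator (\code{","} for CSV; use \code{"\t"} for TSV).
#' @param fe3_initial_mM,culture_volume_mL defaults used for groups whose
#'   rows do not carry these columns; volume defaults to 20 mL (120 mL for
#'   dialysis rows).
#' @return named list of [CultureSeries-class] objects
#'   (names \code{species.condition.mineral.replicate}).
#' @seealso [writeCultureTable()]
#' @export
readCultureTable <- function(path, sep = ",", fe3_initial_mM = 9,
                             culture_volume_mL = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("time_days", "acetate_mM", "fe2_total_mM")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("required column(s) missing: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (meta in c("species", "condition", "mineral", "replicate"))
    if (!meta %in% names(df))
      df[[meta]] <- switch(meta, species = "unknown",
                           condition = "organotrophic", mineral = "HFO",
                           replicate = "r1")
  numcols <- intersect(c("time_days", "cells_per_ml", "ethanol_mM",
                         "acetate_mM", "fe2_total_mM", "fe2_soluble_mM",
                         "fe3_initial_mM", "culture_volume_mL"), names(df))
  for (col in numcols) df[[col]] <- .numericColumn(df[[col]], col)

  key <- interaction(df$species, df$condition, df$mineral, df$replicate,
                     drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, key), function(g) {
    if (anyDuplicated(g$time_days))
      stop(sprintf("duplicate timepoint(s) in group %s/%s/%s/%s",
                   g$species[1], g$condition[1], g$mineral[1],
                   g$replicate[1]), call. = FALSE)
    g <- g[order(g$time_days), , drop = FALSE]
    opt <- function(col) {
      if (!col %in% names(g) || all(is.na(g[[col]]))) numeric(0) else g[[col]]
    }
    fe3 <- if ("fe3_initial_mM" %in% names(g) && !is.na(g$fe3_initial_mM[1]))
      g$fe3_initial_mM[1] else fe3_initial_mM
    vol <- if ("culture_volume_mL" %in% names(g) &&
               !is.na(g$culture_volume_mL[1])) g$culture_volume_mL[1]
      else culture_volume_mL
    CultureSeries(time_days = g$time_days, acetate_mM = g$acetate_mM,
                  fe2_total_mM = g$fe2_total_mM,
                  cell_density = opt("cells_per_ml"),
                  ethanol_mM = opt("ethanol_mM"),
                  fe2_soluble_mM = opt("fe2_soluble_mM"),
                  species_label = g$species[1], condition = g$condition[1],
                  mineral = g$mineral[1], replicate_id = g$replicate[1],
                  fe3_initial_mM = fe3, culture_volume_mL = vol)
  })
  out[order(names(out))]
}

#' Write culture series back to the tabular dialect
#'
#' Inverse of [readCultureTable()]: numeric fields are written with full
#' (17 significant digit) precision so a read/write round trip reproduces
#' them bit-for-bit.
#'
#' @param series a [CultureSeries-class] or list of them.
#' @param path output file path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeCultureTable <- function(series, path, sep = ",") {
  if (is(series, "CultureSeries")) series <- list(series)
  fmt <- function(v, n) {
    if (length(v) == 0L) rep("", n)
    else ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  rows <- lapply(series, function(s) {
    n <- length(s@time_days)
    data.frame(species = s@species_label, condition = s@condition,
               mineral = s@mineral, replicate = s@replicate_id,
               time_days = fmt(s@time_days, n),
               cells_per_ml = fmt(s@cell_density, n),
               ethanol_mM = fmt(s@ethanol_mM, n),
               acetate_mM = fmt(s@acetate_mM, n),
               fe2_total_mM = fmt(s@fe2_total_mM, n),
               fe2_soluble_mM = fmt(s@fe2_soluble_mM, n),
               fe3_initial_mM = fmt(rep(s@fe3_initial_mM, n), n),
               culture_volume_mL = fmt(rep(s@culture_volume_mL, n), n),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a concentration to an amount of substance
#'
#' mM times mL gives micromoles, the unit in which culture-scale electron
#' budgets are reported (e.g. 2.9 mM Fe(II) in a 20 mL culture is 58 umol).
#'
#' @param conc_mM concentration (mM), >= 0.
#' @param volume_mL volume (mL), > 0.
#' @return amount in umol.
#' @examples
#' concentrationToAmount(2.9, 20)  # 58 umol
#' @export
concentrationToAmount <- function(conc_mM, volume_mL) {
  if (any(conc_mM < 0)) stop("conc_mM must be >= 0")
  if (any(volume_mL <= 0)) stop("volume_mL must be > 0")
  conc_mM * volume_mL
}
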