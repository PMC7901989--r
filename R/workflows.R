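#' Culture analysis workflow
#'
#' Ties the culture-side stages together: per-series kinetics (rate fit,
#' plateau, fraction reduced, soluble/sediment split), group statistics
#' (one-way ANOVA + Tukey HSD on a chosen metric across species/condition
#' groups), and the stoichiometric electron budget (theoretical acetate,
#' diverted electrons, diversion efficiency) computed from matched
#' treatment/control series. Reports are written as CSV files under
#' \code{outdir} and returned invisibly; runs are deterministic given
#' identical inputs and parameters.
#'
#' @param series list of [CultureSeries-class] objects, or a path readable
#'   by [readCultureTable()]. Iron-amended series (mineral other than
#'   \code{"none"}) are treatments; \code{"none"} series are their
#'   controls, matched by species and condition.
#' @param outdir output directory (created if needed), or \code{NULL} to
#'   skip writing files.
#' @param metric column of the kinetics report tested across groups
#'   (default \code{"rate_mM_day"}).
#' @param window optional fixed exponential window for every series.
#' @param group_by metadata fields defining the statistical groups.
#' @return invisible list with \code{kinetics}, \code{tukey} (NULL when
#'   fewer than 2 groups or fewer than 2 replicates per group),
#'   and \code{stoichiometry} data.frames.
#' @examples
#' sim <- generateCulture(cultureConfig("gt1-organo", noise_sd = 0), seed = 1)
#' rep <- runCultureWorkflow(c(sim$treatment, sim$control), outdir = NULL)
#' rep$stoichiometry
#' @export
runCultureWorkflow <- function(series, outdir = NULL,
                               metric = "rate_mM_day", window = NULL,
                               group_by = c("species", "condition")) {
  if (is.character(series) && length(series) == 1L)
    series <- readCultureTable(series)
  if (is(series, "CultureSeries")) series <- list(series)
  if (!length(series)) stop("no culture series supplied")
  if (any(vapply(series, function(s) length(timeDays(s)), 1L) < 3))
    stop("every series needs at least 3 timepoints")

  is_treat <- vapply(series, function(s) mineralLabel(s) != "none", TRUE)
  kin <- kineticsReport(series[is_treat], window = window)

  tuk <- NULL
  key <- apply(kin[, group_by, drop = FALSE], 1, paste, collapse = "/")
  groups <- split(kin[[metric]], key)
  if (length(groups) >= 2 && all(vapply(groups, length, 1L) >= 2)) {
    tuk <- pairwiseTable(tukeyHsd(groups))
  } else if (length(series) > 0) {
    warning("fewer than 2 groups with >= 2 replicates: group statistics skipped")
  }

  ## electron budget per (species, condition): mean final acetate amounts
  controls <- series[!is_treat]
  budget <- NULL
  if (length(controls)) {
    gkey <- function(ss) vapply(ss, function(s)
      paste(speciesLabel(s), conditionLabel(s), sep = "/"), "")
    tkeys <- gkey(series[is_treat]); ckeys <- gkey(controls)
    rows <- lapply(intersect(unique(tkeys), unique(ckeys)), function(k) {
      tr <- series[is_treat][tkeys == k]
      co <- controls[ckeys == k]
      lastAcet <- function(s) {
        a <- acetate(s); a <- a[!is.na(a)]
        concentrationToAmount(a[length(a)], cultureVolume(s))
      }
      acet_t <- mean(vapply(tr, lastAcet, 1.0))
      acet_c <- mean(vapply(co, lastAcet, 1.0))
      fe2_umol <- mean(vapply(tr, function(s)
        concentrationToAmount(finalAccumulation(s), cultureVolume(s)), 1.0))
      diverted <- suppressWarnings(acetateDeficitElectrons(acet_c, acet_t))
      eff <- if (diverted > 0)
        diversionEfficiency(fe2_umol, as.numeric(diverted)) else NA_real_
      eth <- ethanol(tr[[1]])
      theo <- if (length(eth) && !is.na(eth[1])) {
        consumed <- concentrationToAmount(max(eth[1] - min(eth, na.rm = TRUE), 0),
                                          cultureVolume(tr[[1]]))
        theoreticalAcetate(consumed)
      } else NA_real_
      data.frame(group = k, control_acetate_umol = acet_c,
                 treatment_acetate_umol = acet_t,
                 theoretical_acetate_umol = theo,
                 diverted_electrons_umol = as.numeric(diverted),
                 fe2_umol = fe2_umol, diversion_efficiency = eff,
                 deficit_flagged = any(attr(diverted, "flagged")),
                 stringsAsFactors = FALSE)
    })
    budget <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(kin, file.path(outdir, "kinetics.csv"),
                     row.names = FALSE)
    if (!is.null(tuk))
      utils::write.csv(tuk, file.path(outdir, "tukey.csv"),
                       row.names = FALSE)
    if (!is.null(budget))
      utils::write.csv(budget, file.path(outdir, "stoichiometry.csv"),
                       row.names = FALSE)
  }
  invisible(list(kinetics = kin, tukey = tuk, stoichiometry = budget))
}

#' Genome analysis workflow
#'
#' Runs the heme-motif survey over one proteome per genome, producing a
#' genome-by-MHC-count summary, per-protein profiles, an optional gene-panel
#' presence matrix and optional assembly statistics. Reports are written as
#' TSV under \code{outdir} when given.
#'
#' @param proteomes named list/vector: genome label -> proteome (FASTA path
#'   or \code{AAStringSet}).
#' @param queries optional panel queries for [panelPresence()].
#' @param contigs optional named list: genome label -> contig FASTA or
#'   \code{DNAStringSet} for [assemblyStats()].
#' @param tier,overlap_policy passed to [proteomeMhcSurvey()].
#' @param outdir output directory or \code{NULL}.
#' @param ... further arguments to [panelPresence()] (thresholds,
#'   \code{strict_paper}).
#' @return invisible list with \code{mhc_summary}, \code{profiles},
#'   \code{panel} (genes x genomes logical matrix or NULL) and
#'   \code{assembly} (data.frame or NULL).
#' @examples
#' pr <- generateProteome(5, list(c("CxxCH", 2)), seed = 1)$proteome
#' runGenomeWorkflow(list(demo = pr))$mhc_summary
#' @export
runGenomeWorkflow <- function(proteomes, queries = NULL, contigs = NULL,
                              tier = "primary_only",
                              overlap_policy = "non_overlapping_greedy",
                              outdir = NULL, ...) {
  if (!length(proteomes)) stop("at least one proteome is required")
  labels <- names(proteomes)
  if (is.null(labels)) labels <- paste0("genome_", seq_along(proteomes))

  surveys <- lapply(proteomes, proteomeMhcSurvey, tier = tier,
                    overlap_policy = overlap_policy)
  mhc_summary <- data.frame(
    genome = labels,
    n_proteins = vapply(surveys, function(s) s$summary$n_proteins, 1L),
    n_mhc = vapply(surveys, function(s) s$summary$n_multiheme, 1L),
    n_mhc_high = vapply(surveys, function(s) s$summary$n_multiheme_high, 1L),
    stringsAsFactors = FALSE)
  profiles <- do.call(rbind, c(lapply(seq_along(surveys), function(i) {
    p <- surveys[[i]]$profiles
    if (nrow(p)) cbind(genome = labels[i], p) else NULL
  }), list(make.row.names = FALSE)))

  panel <- NULL
  if (!is.null(queries)) {
    res <- lapply(proteomes, function(p) panelPresence(queries, p, ...))
    genes <- res[[1]]$gene
    panel <- vapply(res, function(r) r$present[match(genes, r$gene)],
                    logical(length(genes)))
    panel <- matrix(panel, nrow = length(genes),
                    dimnames = list(genes, labels))
  }

  assembly <- NULL
  if (!is.null(contigs)) {
    st <- lapply(contigs, assemblyStats)
    assembly <- data.frame(
      genome = names(st),
      n_contigs = vapply(st, function(x) x@n_contigs, 1L),
      total_length = vapply(st, function(x) x@total_length, 1.0),
      gc_percent = vapply(st, function(x) x@gc_percent, 1.0),
      n50 = vapply(st, function(x) x@n50, 1.0),
      stringsAsFactors = FALSE)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(mhc_summary, "mhc_summary.tsv")
    if (!is.null(profiles)) wt(profiles, "protein_profiles.tsv")
    if (!is.null(panel))
      utils::write.table(panel, file.path(outdir, "panel_matrix.tsv"),
                         sep = "\t", quote = FALSE)
    if (!is.null(assembly)) wt(assembly, "assembly_stats.tsv")
  }
  invisible(list(mhc_summary = mhc_summary, profiles = profiles,
                 panel = panel, assembly = assembly))
}
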