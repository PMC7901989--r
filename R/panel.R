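## Karlin-Altschul parameters for gapped BLOSUM62 with gap open 11 /
## extend 1 (the standard protein-search scoring scheme).
.KA_LAMBDA <- 0.267
.KA_K      <- 0.041

#' Gene-panel presence screening by local alignment
#'
#' Screens a proteome for homologs of each query in a gene panel (e.g. the
#' MHC-conduit panel cymA/mtrABC/pilA/omcS/ppcA/omcB, the flavin-EET panel
#' fmnA/dmkA/fmnB/pplA/ndh2/eetA/eetB/dmkB, or the riboflavin biosynthesis
#' panel ribBA/ribD/ribE/ribF/ribH). Each query is aligned locally
#' (Smith-Waterman, BLOSUM62, gap open 11 / extend 1) against every subject
#' protein; the best raw score defines the hit, its E-value follows
#' Karlin-Altschul statistics (E = K m n exp(-lambda S) with n the summed
#' subject length), and identity is matches over alignment columns.
#'
#' A query is \emph{present} when E-value < \code{evalue}, identity is
#' strictly greater than \code{identity} percent and (unless
#' \code{strict_paper = TRUE}) at least \code{coverage} percent of the query
#' is spanned by the alignment. The coverage condition is a package
#' extension guarding against short spurious local hits; \code{strict_paper}
#' disables it, leaving only the E-value and identity cut-offs.
#'
#' @param queries protein FASTA path, named character vector or
#'   \code{AAStringSet} of panel queries.
#' @param proteome subject proteome, same accepted forms. An empty proteome
#'   yields all-absent results.
#' @param evalue E-value cut-off (default 1e-4).
#' @param identity percent-identity cut-off, strict (default 30).
#' @param coverage minimum percent of the query covered (default 50).
#' @param strict_paper if \code{TRUE}, drop the coverage condition.
#' @return data.frame with one row per query: \code{gene}, \code{best_hit},
#'   \code{score}, \code{identity_pct}, \code{evalue}, \code{coverage_pct},
#'   \code{present}.
#' @examples
#' prot <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSG")
#' panelPresence(c(geneA = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"), prot)
#' @export
panelPresence <- function(queries, proteome, evalue = 1e-4, identity = 30,
                          coverage = 50, strict_paper = FALSE) {
  qset <- .asAAStringSet(queries, "query")
  if (length(qset) == 0L) stop("query set is empty")
  sset <- .asAAStringSet(proteome, "proteome")
  qn <- names(qset)
  if (is.null(qn)) qn <- paste0("query_", seq_along(qset))
  if (length(sset) == 0L) {
    return(data.frame(gene = qn, best_hit = NA_character_, score = NA_real_,
                      identity_pct = NA_real_, evalue = NA_real_,
                      coverage_pct = NA_real_, present = FALSE,
                      stringsAsFactors = FALSE))
  }
  sn <- names(sset)
  if (is.null(sn)) sn <- paste0("subject_", seq_along(sset))
  db_len <- sum(Biostrings::width(sset))

  rows <- lapply(seq_along(qset), function(qi) {
    q <- qset[[qi]]
    qlen <- length(q)
    aln <- Biostrings::pairwiseAlignment(
      pattern = sset, subject = q, type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    best <- which.max(sc)
    a <- aln[best]
    s <- sc[best]
    ev <- .KA_K * qlen * db_len * exp(-.KA_LAMBDA * s)
    idpct <- Biostrings::pid(a, type = "PID1")
    cov <- 100 * (BiocGenerics::end(Biostrings::subject(a)) -
                  BiocGenerics::start(Biostrings::subject(a)) + 1) / qlen
    present <- ev < evalue && idpct > identity &&
      (strict_paper || cov >= coverage)
    data.frame(gene = qn[qi], best_hit = sn[best], score = s,
               identity_pct = idpct, evalue = ev, coverage_pct = cov,
               present = present, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
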