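## 20 standard residues; ambiguity codes X/B/Z/U match wildcard positions
## only, never anchors; '*' terminates the segment being scanned.
.AA_STANDARD  <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA_WILDCARD  <- c(.AA_STANDARD, "X", "B", "Z", "U")
.AA_ALLOWED   <- c(.AA_WILDCARD, "*")

#' Heme-binding motif patterns
#'
#' The six heme c attachment motifs used by the survey: the canonical
#' CxxCH (primary tier) and the variants CxxxCH, CxxxxCH, CxxCK, AxxCH and
#' FxxCH ("A/FxxCH" expanded literally into two single-cysteine patterns).
#' Anchor residues are matched exactly; \code{x} positions accept any
#' standard residue or ambiguity code. The list order encodes the
#' most-canonical-first precedence used by combined greedy scanning.
#'
#' @param tier \code{"primary_only"} (CxxCH alone) or \code{"with_variants"}
#'   (all six).
#' @return named list of pattern descriptors (\code{name}, \code{length},
#'   \code{anchors} = named character vector position -> residue,
#'   \code{tier}).
#' @examples
#' names(motifPatterns("with_variants"))
#' @export
motifPatterns <- function(tier = c("with_variants", "primary_only")) {
  tier <- match.arg(tier)
  mk <- function(name, len, anchors, tr)
    list(name = name, length = len, anchors = anchors, tier = tr)
  pats <- list(
    CxxCH   = mk("CxxCH",   5L, c("1" = "C", "4" = "C", "5" = "H"), "primary"),
    CxxxCH  = mk("CxxxCH",  6L, c("1" = "C", "5" = "C", "6" = "H"), "variant"),
    CxxxxCH = mk("CxxxxCH", 7L, c("1" = "C", "6" = "C", "7" = "H"), "variant"),
    CxxCK   = mk("CxxCK",   5L, c("1" = "C", "4" = "C", "5" = "K"), "variant"),
    AxxCH   = mk("AxxCH",   5L, c("1" = "A", "4" = "C", "5" = "H"), "variant"),
    FxxCH   = mk("FxxCH",   5L, c("1" = "F", "4" = "C", "5" = "H"), "variant")
  )
  if (tier == "primary_only") pats["CxxCH"] else pats
}

## All match start positions of one pattern over a character vector,
## vectorised; '*' fails both anchor and wildcard tests, so matches never
## straddle a stop.
.matchStarts <- function(cs, pat) {
  L <- length(cs)
  if (L < pat$length) return(integer(0))
  starts <- seq_len(L - pat$length + 1L)
  ok <- rep(TRUE, length(starts))
  anchor_pos <- as.integer(names(pat$anchors))
  for (o in seq_len(pat$length)) {
    at <- cs[starts + o - 1L]
    ok <- ok & if (o %in% anchor_pos) at == pat$anchors[[as.character(o)]]
               else at %in% .AA_WILDCARD
  }
  starts[ok]
}

#' Scan a protein sequence for heme-binding motifs
#'
#' Under \code{"non_overlapping_greedy"} (the default) the sequence is
#' scanned left to right; at each position the patterns are tried in their
#' list order (most canonical first) and a hit advances the scan past the
#' matched residues, so one cysteine never serves two hemes. Under
#' \code{"all_positions"} every matching start position of every pattern is
#' reported.
#'
#' @param sequence amino-acid string (20-letter alphabet plus X, B, Z, U
#'   and \code{*}; case-insensitive). An empty string yields an empty hit
#'   table; characters outside the alphabet raise an error.
#' @param patterns pattern list from [motifPatterns()].
#' @param overlap_policy \code{"non_overlapping_greedy"} or
#'   \code{"all_positions"}.
#' @return data.frame with columns \code{pattern}, \code{start} (1-based),
#'   \code{match}.
#' @examples
#' scanMotifs("MCAACHGGGCAACHD", motifPatterns("primary_only"))
#' scanMotifs("CAACHACH", motifPatterns("primary_only"),
#'            overlap_policy = "all_positions")
#' @export
scanMotifs <- function(sequence, patterns = motifPatterns(),
                       overlap_policy = c("non_overlapping_greedy",
                                          "all_positions")) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  cs <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(cs), .AA_ALLOWED)
  if (length(bad))
    stop(sprintf("illegal character(s) in sequence: %s",
                 paste(bad, collapse = ", ")))
  empty <- data.frame(pattern = character(0), start = integer(0),
                      match = character(0), stringsAsFactors = FALSE)
  if (length(cs) == 0L) return(empty)

  if (overlap_policy == "all_positions") {
    rows <- lapply(patterns, function(p) {
      st <- .matchStarts(cs, p)
      if (!length(st)) return(NULL)
      data.frame(pattern = p$name, start = st,
                 match = vapply(st, function(s)
                   paste(cs[s:(s + p$length - 1L)], collapse = ""), ""),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(empty)
    rownames(out) <- NULL
    return(out[order(out$start, match(out$pattern, names(patterns))), ,
               drop = FALSE])
  }

  ## greedy: precompute per-pattern match positions, then sweep
  match_sets <- lapply(patterns, function(p) .matchStarts(cs, p))
  hits <- list()
  pos <- 1L
  L <- length(cs)
  while (pos <= L) {
    advanced <- FALSE
    for (pi in seq_along(patterns)) {
      if (pos %in% match_sets[[pi]]) {
        p <- patterns[[pi]]
        hits[[length(hits) + 1L]] <- data.frame(
          pattern = p$name, start = pos,
          match = paste(cs[pos:(pos + p$length - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
        pos <- pos + p$length
        advanced <- TRUE
        break
      }
    }
    if (!advanced) pos <- pos + 1L
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Classify a protein by its heme-binding motif count
#'
#' Multiheme c-type cytochrome (MHC) candidates carry at least two
#' heme-binding motifs; six or more marks the high-heme class typical of
#' dedicated extracellular electron conduits.
#'
#' @param count non-negative motif count.
#' @return \code{"none"}, \code{"monoheme"}, \code{"multiheme"} (2-5) or
#'   \code{"multiheme_high"} (>= 6).
#' @examples
#' classifyProtein(2)
#' @export
classifyProtein <- function(count) {
  if (any(count < 0)) stop("count must be >= 0")
  ifelse(count == 0, "none",
         ifelse(count == 1, "monoheme",
                ifelse(count <= 5, "multiheme", "multiheme_high")))
}

.asAAStringSet <- function(x, what = "proteome") {
  if (is(x, "AAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    out <- tryCatch(Biostrings::readAAStringSet(x),
                    error = function(e)
                      stop(sprintf("failed to parse %s FASTA '%s': %s",
                                   what, x, conditionMessage(e)),
                           call. = FALSE))
    return(out)
  }
  if (is.character(x)) return(Biostrings::AAStringSet(x))
  stop(sprintf("cannot interpret %s input of class %s", what, class(x)[1]))
}

#' Survey a proteome for multiheme c-type cytochromes
#'
#' Scans every protein for heme-binding motifs and classifies it by motif
#' count. Under \code{tier = "primary_only"} only CxxCH counts toward the
#' classification; under \code{"with_variants"} all six patterns are scanned
#' with combined greedy precedence (CxxCH first) and the combined count
#' classifies.
#'
#' @param proteome protein FASTA path, named character vector, or
#'   \code{AAStringSet}.
#' @param tier \code{"primary_only"} or \code{"with_variants"}.
#' @param overlap_policy passed to [scanMotifs()].
#' @return list with \code{profiles} (data.frame: protein_id, length,
#'   count per pattern, count_total, classification) and \code{summary}
#'   (n_proteins, n_multiheme, n_multiheme_high).
#' @examples
#' pr <- generateProteome(n_decoys = 5,
#'                        planted = list(c("CxxCH", 2)), seed = 1)
#' proteomeMhcSurvey(pr$proteome, tier = "primary_only")$summary
#' @export
proteomeMhcSurvey <- function(proteome,
                              tier = c("primary_only", "with_variants"),
                              overlap_policy = "non_overlapping_greedy") {
  tier <- match.arg(tier)
  aa <- .asAAStringSet(proteome)
  pats <- motifPatterns(if (tier == "primary_only") "primary_only"
                        else "with_variants")
  ids <- names(aa)
  if (is.null(ids)) ids <- paste0("protein_", seq_along(aa))
  if (length(aa) == 0L) {
    empty <- data.frame(protein_id = character(0), length = integer(0),
                        count_total = integer(0),
                        classification = character(0),
                        stringsAsFactors = FALSE)
    return(list(profiles = empty,
                summary = list(n_proteins = 0L, n_multiheme = 0L,
                               n_multiheme_high = 0L)))
  }
  profiles <- lapply(seq_along(aa), function(i) {
    seqchr <- as.character(aa[[i]])
    hits <- scanMotifs(seqchr, pats, overlap_policy = overlap_policy)
    counts <- vapply(names(pats),
                     function(pn) sum(hits$pattern == pn), 1L)
    total <- nrow(hits)
    row <- data.frame(protein_id = ids[i], length = nchar(seqchr),
                      stringsAsFactors = FALSE)
    for (pn in names(pats)) row[[paste0("count_", pn)]] <- counts[[pn]]
    row$count_total <- total
    row$classification <- classifyProtein(total)
    row
  })
  profiles <- do.call(rbind, c(profiles, list(make.row.names = FALSE)))
  if (is.null(profiles))
    profiles <- data.frame(protein_id = character(0), length = integer(0),
                           count_total = integer(0),
                           classification = character(0),
                           stringsAsFactors = FALSE)
  list(profiles = profiles,
       summary = list(
         n_proteins = length(aa),
         n_multiheme = sum(profiles$classification %in%
                             c("multiheme", "multiheme_high")),
         n_multiheme_high = sum(profiles$classification == "multiheme_high")))
}

#' Assembly statistics of a contig set
#'
#' @param contigs nucleotide FASTA path or \code{DNAStringSet}
#'   (A/C/G/T/N alphabet; at least one contig).
#' @return an [AssemblyStats-class]: contig count, total length, GC percent
#'   over unambiguous bases, and N50.
#' @examples
#' assemblyStats(Biostrings::DNAStringSet(c(a = "ATGC", b = strrep("G", 300))))
#' @export
assemblyStats <- function(contigs) {
  dna <- if (is(contigs, "DNAStringSet")) contigs
         else Biostrings::readDNAStringSet(contigs)
  if (length(dna) == 0L) stop("assembly contains no contigs")
  lens <- Biostrings::width(dna)
  total <- sum(lens)
  freq <- colSums(Biostrings::alphabetFrequency(dna,
                                                baseOnly = TRUE))[c("A", "C", "G", "T")]
  gc <- 100 * sum(freq[c("G", "C")]) / sum(freq)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  new("AssemblyStats", n_contigs = length(dna), total_length = as.numeric(total),
      gc_percent = gc, n50 = as.numeric(n50))
}
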