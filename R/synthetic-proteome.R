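## Residues used for wildcard positions inside planted motifs: standard
## residues that can never complete an anchor of any pattern.
.SAFE_RESIDUES <- strsplit("DEGILMNQSTV", "")[[1]]

.randomSeq <- function(len, alphabet = .AA_STANDARD) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

.motifFreeSeq <- function(len, patterns, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    s <- .randomSeq(len)
    if (nrow(scanMotifs(s, patterns, overlap_policy = "all_positions")) == 0L)
      return(s)
  }
  stop("failed to sample a motif-free sequence")  # practically unreachable
}

.motifInstance <- function(pat) {
  out <- sample(.SAFE_RESIDUES, pat$length, replace = TRUE)
  for (o in names(pat$anchors)) out[as.integer(o)] <- pat$anchors[[o]]
  out
}

## One protein carrying exactly `count` non-overlapping copies of `pat`
## and no other motif match of any pattern (verified; resampled on
## accidental extra matches).
.plantedSeq <- function(pat, count, len, all_patterns, max_tries = 200) {
  slack <- len - count * pat$length
  if (slack < 0)
    stop(sprintf("cannot plant %d x %s in a length-%d protein",
                 count, pat$name, len))
  for (i in seq_len(max_tries)) {
    cs <- strsplit(.motifFreeSeq(len, all_patterns), "")[[1]]
    ## random non-overlapping starts: sorted offsets into the slack, each
    ## shifted by the residues already occupied by earlier copies
    x <- sort(sample.int(slack + 1L, count, replace = TRUE)) - 1L
    starts <- x + (seq_len(count) - 1L) * pat$length + 1L
    for (st in starts)
      cs[st:(st + pat$length - 1L)] <- .motifInstance(pat)
    s <- paste(cs, collapse = "")
    hits <- scanMotifs(s, all_patterns, overlap_policy = "all_positions")
    if (nrow(hits) == count && all(hits$pattern == pat$name) &&
        setequal(hits$start, starts))
      return(list(seq = s, starts = sort(starts)))
  }
  stop("failed to plant motifs without accidental extra matches")
}

#' Generate a proteome with planted heme-binding motifs
#'
#' Builds a synthetic protein FASTA with known ground truth: decoy proteins
#' rejection-sampled to contain zero matches of any of the six heme-binding
#' patterns (under all-positions scanning), plus planted proteins carrying
#' exactly the requested number of non-overlapping copies of a pattern at
#' recorded positions. Record order is shuffled and identifiers are opaque,
#' so nothing about the ground truth leaks through the FASTA itself.
#'
#' @param n_decoys number of motif-free decoy proteins (>= 0).
#' @param planted list of \code{c(pattern_name, count)} pairs, e.g.
#'   \code{list(c("CxxCH", 2), c("CxxCH", 6))}; one planted protein per
#'   entry. Counts of 0 plant a motif-free protein.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param decoy_length_range min/max decoy length (residues).
#' @param planted_length length of planted proteins; \code{NULL} scales
#'   with the motif load. Planting more motif residues than fit raises an
#'   error.
#' @return list with \code{proteome} (\code{AAStringSet}) and \code{truth}
#'   (data.frame: protein_id, pattern, count, positions).
#' @examples
#' pr <- generateProteome(10, list(c("CxxCH", 2), c("CxxCH", 6)), seed = 3)
#' pr$truth
#' @export
generateProteome <- function(n_decoys, planted = list(), seed = 1,
                             decoy_length_range = c(120, 350),
                             planted_length = NULL) {
  if (n_decoys < 0) stop("n_decoys must be >= 0")
  pats <- motifPatterns("with_variants")
  for (pl in planted) {
    if (!pl[[1]] %in% names(pats))
      stop(sprintf("unknown pattern '%s'", pl[[1]]))
    if (as.integer(pl[[2]]) < 0) stop("planted counts must be >= 0")
  }
  .withSeed(seed, {
    entries <- list()
    truth_rows <- list()
    for (i in seq_along(planted)) {
      pname <- planted[[i]][[1]]
      count <- as.integer(planted[[i]][[2]])
      pat <- pats[[pname]]
      len <- if (!is.null(planted_length)) planted_length
             else max(80L, count * (pat$length + 10L) + 40L)
      if (count * pat$length > len)
        stop(sprintf("infeasible plant: %d x %s (%d residues) exceeds protein length %d",
                     count, pname, count * pat$length, len))
      if (count == 0L) {
        entries[[length(entries) + 1L]] <-
          list(seq = .motifFreeSeq(len, pats), pattern = pname, count = 0L,
               positions = "")
      } else {
        ps <- .plantedSeq(pat, count, len, pats)
        entries[[length(entries) + 1L]] <-
          list(seq = ps$seq, pattern = pname, count = count,
               positions = paste(ps$starts, collapse = ","))
      }
    }
    for (i in seq_len(n_decoys)) {
      len <- sample(seq(decoy_length_range[1], decoy_length_range[2]), 1L)
      entries[[length(entries) + 1L]] <-
        list(seq = .motifFreeSeq(len, pats), pattern = NA_character_,
             count = 0L, positions = "")
    }
    if (!length(entries))
      return(list(proteome = Biostrings::AAStringSet(),
                  truth = data.frame(protein_id = character(0),
                                     pattern = character(0),
                                     count = integer(0),
                                     positions = character(0),
                                     stringsAsFactors = FALSE)))
    ord <- sample(length(entries))
    entries <- entries[ord]
    ids <- sprintf("prot_%04d", seq_along(entries))
    aa <- Biostrings::AAStringSet(vapply(entries, `[[`, "", "seq"))
    names(aa) <- ids
    truth <- data.frame(
      protein_id = ids,
      pattern = vapply(entries, `[[`, "", "pattern"),
      count = vapply(entries, `[[`, 1L, "count"),
      positions = vapply(entries, `[[`, "", "positions"),
      stringsAsFactors = FALSE)
    list(proteome = aa, truth = truth)
  })
}
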