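pats_all <- motifPatterns("with_variants")
pats_primary <- motifPatterns("primary_only")

test_that("worked motif-scan examples behave as documented", {
  hits <- scanMotifs("MCAACHGGGCAACHD", pats_primary)
  expect_equal(hits$start, c(2L, 10L))
  expect_equal(hits$pattern, c("CxxCH", "CxxCH"))
  expect_equal(hits$match, c("CAACH", "CAACH"))

  greedy <- scanMotifs("CAACHACH", pats_primary)
  expect_equal(greedy$start, 1L)
  all_pos <- scanMotifs("CAACHACH", pats_primary,
                        overlap_policy = "all_positions")
  expect_equal(all_pos$start, c(1L, 4L))

  v <- scanMotifs("CAACK", pats_all)
  expect_equal(v$pattern, "CxxCK")
  expect_equal(v$start, 1L)
  expect_equal(nrow(scanMotifs("CAACK", pats_primary)), 0)
})

test_that("ambiguity codes match wildcards only and '*' stops a segment", {
  # X in a wildcard slot is fine; X in an anchor slot is not a match
  expect_equal(scanMotifs("CXXCH", pats_primary)$start, 1L)
  expect_equal(nrow(scanMotifs("XAACH", pats_primary)), 0)
  # a stop codon between the cysteines kills the match
  expect_equal(nrow(scanMotifs("CA*CH", pats_primary)), 0)
  expect_equal(scanMotifs("CAACH*CAACH", pats_primary)$start, c(1L, 7L))
  expect_equal(nrow(scanMotifs("", pats_primary)), 0)
  expect_error(scanMotifs("CAJCH", pats_primary), "illegal")
})

test_that("all-positions scanning equals brute-force enumeration", {
  set.seed(77)
  for (i in 1:200) {
    s <- random_protein(sample(30:200, 1))
    hits <- scanMotifs(s, pats_all, overlap_policy = "all_positions")
    for (pn in names(pats_all)) {
      expect_equal(sort(hits$start[hits$pattern == pn]),
                   oracle_motif_positions(s, pn),
                   info = sprintf("pattern %s, seq %s", pn, s))
    }
  }
})

test_that("greedy hit count never exceeds the all-positions count", {
  set.seed(78)
  for (i in 1:50) {
    s <- random_protein(sample(50:200, 1))
    expect_lte(nrow(scanMotifs(s, pats_all)),
               nrow(scanMotifs(s, pats_all, overlap_policy = "all_positions")))
  }
})

test_that("greedy precedence prefers the canonical pattern", {
  # CAACH matches both CxxCH and (as a prefix window) nothing else; at a
  # site matching CxxCH and AxxCH starts, CxxCH is consumed first
  h <- scanMotifs("CAACHAAACH", pats_all)
  expect_equal(h$pattern[1], "CxxCH")
})

test_that("no hidden strand logic: reversal loses non-palindromic hits", {
  s <- "GGGCAACHGGG"
  rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(nrow(scanMotifs(s, pats_primary)), 1)
  expect_equal(nrow(scanMotifs(rs, pats_primary)), 0)
})

test_that("motif-count classification follows the MHC thresholds", {
  expect_identical(classifyProtein(0), "none")
  expect_identical(classifyProtein(1), "monoheme")
  expect_identical(classifyProtein(2), "multiheme")
  expect_identical(classifyProtein(5), "multiheme")
  expect_identical(classifyProtein(6), "multiheme_high")
  expect_error(classifyProtein(-1), ">= 0")
})

test_that("proteome surveys recover planted ground truth", {
  pr <- generateProteome(50, list(c("CxxCH", 2), c("CxxCH", 6)), seed = 9)
  sv <- proteomeMhcSurvey(pr$proteome, tier = "primary_only")
  expect_equal(sv$summary$n_proteins, 52L)
  expect_equal(sv$summary$n_multiheme, 2L)
  expect_equal(sv$summary$n_multiheme_high, 1L)
  # per-protein counts match the truth table exactly
  planted <- pr$truth[pr$truth$count > 0, ]
  prof <- sv$profiles
  expect_equal(prof$count_total[match(planted$protein_id, prof$protein_id)],
               planted$count)
  empty <- proteomeMhcSurvey(Biostrings::AAStringSet())
  expect_equal(empty$summary$n_multiheme, 0L)
})

test_that("survey counts are invariant to record order and line wrapping", {
  pr <- generateProteome(10, list(c("CxxxCH", 3)), seed = 21)
  f1 <- withr::local_tempfile(fileext = ".faa")
  f2 <- withr::local_tempfile(fileext = ".faa")
  Biostrings::writeXStringSet(pr$proteome, f1, width = 60)
  Biostrings::writeXStringSet(rev(pr$proteome), f2, width = 13)
  s1 <- proteomeMhcSurvey(f1, tier = "with_variants")
  s2 <- proteomeMhcSurvey(f2, tier = "with_variants")
  expect_equal(s1$summary, s2$summary)
  o <- order(s1$profiles$protein_id)
  o2 <- order(s2$profiles$protein_id)
  expect_equal(s1$profiles[o, ], s2$profiles[o2, ], ignore_attr = TRUE)
})

test_that("assembly statistics match hand checks and the N50 oracle", {
  two <- Biostrings::DNAStringSet(c(a = strrep("A", 100),
                                    b = strrep("GC", 150)))
  st <- assemblyStats(two)
  expect_equal(st@n_contigs, 2L)
  expect_equal(st@total_length, 400)
  expect_equal(st@n50, 300)
  expect_equal(assemblyStats(Biostrings::DNAStringSet(c(x = "ATGC")))@gc_percent,
               50)
  # N excluded from the GC denominator
  expect_equal(assemblyStats(Biostrings::DNAStringSet(c(x = "ATGCNN")))@gc_percent,
               50)
  expect_error(assemblyStats(Biostrings::DNAStringSet()), "no contigs")

  set.seed(12)
  for (i in 1:30) {
    lens <- sample(50:5000, sample(3:40, 1), replace = TRUE)
    contigs <- Biostrings::DNAStringSet(vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      ""))
    st <- assemblyStats(contigs)
    expect_equal(st@n50, oracle_n50(lens))
    expect_equal(st@total_length, sum(lens))
  }
})

test_that("panel screening: self-hits present, shuffled nulls absent", {
  set.seed(31)
  q <- c(geneA = random_protein(220))
  prot <- Biostrings::AAStringSet(c(p1 = unname(q), p2 = random_protein(300)))
  res <- panelPresence(q, prot)
  expect_true(res$present)
  expect_equal(res$best_hit, "p1")
  expect_equal(res$identity_pct, 100)
  expect_lt(res$evalue, 1e-10)

  # shuffle null: length-matched permutations of the query never pass
  shuffles <- vapply(1:100, function(i)
    paste(sample(strsplit(unname(q), "")[[1]]), collapse = ""), "")
  names(shuffles) <- paste0("shuf_", 1:100)
  nullres <- panelPresence(q, shuffles)
  expect_false(nullres$present)
})

test_that("panel thresholds are strict and the empty proteome is all-absent", {
  q <- c(g = random_protein(150))
  # identity must be strictly greater than the cut-off: a perfect self hit
  # at threshold 100 is still absent
  res <- panelPresence(q, q, identity = 100)
  expect_false(res$present)
  expect_equal(res$identity_pct, 100)

  none <- panelPresence(q, Biostrings::AAStringSet())
  expect_false(none$present)
  expect_true(is.na(none$best_hit))

  # strict_paper drops the coverage condition
  half <- substr(unname(q), 1, 40)
  res2 <- panelPresence(c(g = paste0(unname(q), random_protein(150))),
                        c(s = half), strict_paper = TRUE)
  expect_lt(res2$coverage_pct, 50)
})
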