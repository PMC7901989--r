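# Independent oracles used across the suite. Each deliberately takes a
# different code path from the implementation it checks.

# Brute-force motif matcher via per-pattern regex with lookahead (finds
# overlapping matches); wildcard = standard residues + ambiguity codes.
oracle_motif_positions <- function(sequence, pattern_name) {
  wc <- "[ACDEFGHIKLMNPQRSTVWYXBZU]"
  rx <- switch(pattern_name,
    CxxCH   = paste0("C", wc, wc, "CH"),
    CxxxCH  = paste0("C", wc, wc, wc, "CH"),
    CxxxxCH = paste0("C", wc, wc, wc, wc, "CH"),
    CxxCK   = paste0("C", wc, wc, "CK"),
    AxxCH   = paste0("A", wc, wc, "CH"),
    FxxCH   = paste0("F", wc, wc, "CH"),
    stop("unknown pattern"))
  m <- gregexpr(paste0("(?=", rx, ")"), toupper(sequence), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# N50 by definition-chasing over candidate lengths (no cumulative scan):
# the largest observed length L such that contigs >= L cover half the total.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  min(lengths)
}

# Exhaustive exponential-window enumeration via lm()/summary(), mirroring
# the selection contract (window must contain the steepest log-density
# step; max R^2; ties within tol -> longer, then earlier).
oracle_exp_window <- function(t, dens, min_points = 3, tie_tol = 0.005) {
  y <- log10(dens)
  n <- length(t)
  steps <- diff(y) / diff(t)
  peak <- which(steps >= max(steps) - 1e-9)
  rows <- list()
  for (len in min_points:n) {
    for (start in seq_len(n - len + 1)) {
      idx <- start:(start + len - 1)
      if (length(unique(y[idx])) == 1L) next
      if (!any(peak %in% idx[-length(idx)])) next
      fit <- summary(lm(y[idx] ~ t[idx]))
      rows[[length(rows) + 1L]] <- c(r2 = fit$r.squared, len = len,
                                     start = start)
    }
  }
  m <- do.call(rbind, rows)
  m <- m[m[, "r2"] >= max(m[, "r2"]) - tie_tol, , drop = FALSE]
  m <- m[m[, "len"] == max(m[, "len"]), , drop = FALSE]
  b <- m[which.min(m[, "start"]), ]
  c(t[b[["start"]]], t[b[["start"]] + b[["len"]] - 1])
}

# One-way ANOVA from explicit sums of squares.
oracle_anova_f <- function(groups) {
  vals <- unlist(groups)
  grand <- mean(vals)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, 1.0))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  df_b <- length(groups) - 1
  df_w <- length(vals) - length(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = pf(f, df_b, df_w, lower.tail = FALSE))
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
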