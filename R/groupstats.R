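.checkGroups <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2)
    stop("groups must be a named list of at least 2 numeric vectors")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 values")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L)
    stop("all values identical: variance is degenerate")
  invisible(groups)
}

#' One-way analysis of variance across groups
#'
#' Classical fixed-effects one-way ANOVA (via [stats::aov()]) of replicate
#' values across species/condition groups.
#'
#' @param groups named list mapping group label to a numeric vector of
#'   replicate values (>= 2 groups, >= 2 values each).
#' @return list with elements \code{f} and \code{p}.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(8, 9, 10)))
#' @export
oneWayAnova <- function(groups) {
  .checkGroups(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L))))
  tab <- summary(stats::aov(value ~ group, data = df))[[1]]
  list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
}

.pStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Tukey's honest significant difference test
#'
#' Pairwise comparisons of group means with studentized-range adjusted
#' p-values, computed from the group summaries and the pooled within-group
#' mean square via [stats::ptukey()]. Uses the Tukey-Kramer standard error
#' so unequal replicate numbers are handled. Stars mirror the figure-legend
#' convention: \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05.
#'
#' @param groups named list of numeric replicate vectors, as for
#'   [oneWayAnova()].
#' @param alpha significance level; affects flags only, not the statistics.
#' @return a [GroupComparison-class].
#' @examples
#' tukeyHsd(list(gt1 = c(0.47, 0.5, 0.44), woodii = c(0.11, 0.09, 0.1)))
#' @export
tukeyHsd <- function(groups, alpha = 0.05) {
  .checkGroups(groups)
  aov_res <- oneWayAnova(groups)
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1.0)
  df_err <- sum(ns) - k
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1.0)) / df_err
  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    d <- means[[i]] - means[[j]]
    se <- sqrt((mse / 2) * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    data.frame(pair = paste(i, j, sep = "-"), diff = d, q = q, p_adj = p,
               stars = .pStars(p), significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  new("GroupComparison", group_labels = names(groups), group_values = groups,
      f_statistic = aov_res$f, anova_p = aov_res$p,
      pairwise = do.call(rbind, rows))
}

#' Pairwise comparison table of a GroupComparison
#'
#' @param x a [GroupComparison-class].
#' @return the pairwise data.frame (pair, mean difference, q, adjusted p,
#'   stars).
#' @export
pairwiseTable <- function(x) {
  stopifnot(is(x, "GroupComparison"))
  x@pairwise
}
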