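# Self-contained statistical primitives used by all pipeline stages:
# hypergeometric overlap tails, BH adjustment, an exact r x c Fisher test by
# exhaustive enumeration, the adjusted Rand index, and rank tests.

test_result <- function(method, statistic, p_value, inputs = list()) {
  tibble(method = method, statistic = statistic, p_value = p_value,
         inputs = list(inputs))
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing an overlap of at least `k` genes between a set of
#' size `n1` and a set of size `n2` drawn from a universe of `N` genes:
#' `P(X >= k)` for `X ~ Hypergeometric(N, n1, n2)`. This is the enrichment
#' test behind the directional overlap matrices.
#'
#' @param k Observed overlap count.
#' @param n1,n2 Sizes of the two gene sets.
#' @param N Universe size.
#' @return One-row tibble with `method`, `statistic` (= k), `p_value`.
#' @export
hypergeom_tail <- function(k, n1, n2, N) {
  if (any(c(k, n1, n2, N) < 0) || k > min(n1, n2) || max(n1, n2) > N) {
    abort("require 0 <= k <= min(n1, n2) <= N.")
  }
  p <- if (k == 0) 1 else phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  test_result("hypergeometric upper tail", statistic = as.numeric(k),
              p_value = min(1, p),
              inputs = list(k = k, n1 = n1, n2 = n2, N = N))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; a thin, input-checked wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`; `NaN` is rejected.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.nan(p_values))) abort("NaN p-values are not allowed.")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Exact Fisher test on an r x c contingency table
#'
#' Two-sided exact test by exhaustive enumeration of all tables with the
#' observed margins: the p-value is the total conditional (multivariate
#' hypergeometric) probability of tables no more probable than the observed
#' one. Intended for desk-scale tables such as a sex-by-subgroup 3 x 2 table;
#' tables whose enumeration would exceed `cap` raise an error.
#'
#' @param table Non-negative integer matrix (r x c) with at least one
#'   positive margin.
#' @param cap Maximum number of candidate tables to enumerate (default 5e7).
#' @return One-row tibble with `method`, `statistic` (number of tables
#'   enumerated) and `p_value`.
#' @export
fisher_exact_rxc <- function(table, cap = 5e7) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("table entries must be non-negative integers.")
  }
  if (sum(tab) == 0) abort("table must have at least one positive margin.")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  N <- sum(tab)
  r <- nrow(tab)
  cc <- ncol(tab)

  # cheap upper bound on the number of margin-fixed tables: compositions of
  # each of the first r-1 row margins into cc parts, ignoring column caps
  bound <- prod(choose(rs[-r] + cc - 1, cc - 1))
  if (!is.finite(bound) || bound > cap) {
    abort(sprintf(
      "table too large for exact enumeration (bound %.3g tables > cap %.3g).",
      bound, cap))
  }

  # log conditional probability of a margin-fixed table
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  log_prob <- function(m) log_const - sum(lgamma(m + 1))

  lp_obs <- log_prob(tab)
  tol <- 1e-7
  acc <- new.env()
  acc$p <- 0
  acc$count <- 0L

  # enumerate compositions of `total` into parts bounded by `caps`
  compositions <- function(total, caps) {
    k <- length(caps)
    if (k == 1) {
      if (total <= caps[1]) return(list(total)) else return(list())
    }
    out <- list()
    for (v in 0:min(total, caps[1])) {
      rest <- compositions(total - v, caps[-1])
      for (z in rest) out[[length(out) + 1L]] <- c(v, z)
    }
    out
  }

  recurse <- function(row_idx, col_left, rows_acc) {
    if (row_idx == r) {
      if (any(col_left < 0)) return(invisible())
      m <- rbind(rows_acc, col_left)
      acc$count <- acc$count + 1L
      if (acc$count > cap) abort("enumeration exceeded the table cap.")
      lp <- log_prob(m)
      if (lp <= lp_obs + tol) acc$p <- acc$p + exp(lp)
      return(invisible())
    }
    for (comp in compositions(rs[row_idx], pmin(col_left, rs[row_idx]))) {
      recurse(row_idx + 1L, col_left - comp,
              rbind(rows_acc, comp, deparse.level = 0))
    }
    invisible()
  }
  recurse(1L, cs, matrix(numeric(0), nrow = 0, ncol = cc))

  test_result("Fisher exact (exhaustive enumeration)",
              statistic = as.numeric(acc$count),
              p_value = min(1, acc$p),
              inputs = list(table = tab))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples,
#' using the permutation-model correction on the pair-counting Rand index.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return A single number in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("label vectors must have equal length.")
  }
  n <- length(labels_a)
  if (n < 2) return(1)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return One-row tibble with the chi-square-approximation statistic and
#'   p-value; identical values everywhere yield `p = 1` by convention.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("need at least 2 non-empty groups.")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1) {
    return(test_result("Kruskal-Wallis rank sum test", 0, 1,
                       inputs = list(n = lengths(groups))))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- kruskal.test(values, g)
  test_result("Kruskal-Wallis rank sum test",
              statistic = unname(fit$statistic),
              p_value = fit$p.value,
              inputs = list(n = lengths(groups)))
}

#' Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Two-sided; exact enumeration when both samples have at most 10
#' observations and no ties, otherwise the normal approximation with midrank
#' tie correction (no continuity correction).
#'
#' @param x,y Non-empty numeric vectors.
#' @return One-row tibble with the rank-sum statistic (W) and p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty.")
  values <- c(x, y)
  if (length(unique(values)) == 1) {
    return(test_result("Wilcoxon rank sum test", length(x) * length(y) / 2, 1,
                       inputs = list(n = c(length(x), length(y)))))
  }
  has_ties <- anyDuplicated(values) > 0
  use_exact <- length(x) <= 10 && length(y) <= 10 && !has_ties
  fit <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  test_result("Wilcoxon rank sum test",
              statistic = unname(fit$statistic),
              p_value = fit$p.value,
              inputs = list(n = c(length(x), length(y)), exact = use_exact))
}
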