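# Marker-based cell-type deconvolution of bulk expression (digital sorting):
# TMM scale factors, marker selection by expression specificity, proportion
# estimation from marker means under a sum-to-one constraint, group
# comparisons of the estimated proportions, and variance-explained summaries.

#' TMM (trimmed mean of M-values) scale factors
#'
#' Per-sample scale factors for between-sample normalization of counts. The
#' reference is the sample whose upper-quartile (of counts over library
#' size) is closest to the mean upper-quartile; each sample's factor is the
#' doubly trimmed, precision-weighted mean of log2 ratios against the
#' reference (trimming `trim_m` of M-values and `trim_a` of A-values on each
#' side), exponentiated and normalized so the factors' geometric mean is 1.
#' Factors absorb library size: dividing each sample by its factor puts all
#' samples on a common scale.
#'
#' @param counts Count-scale expression matrix.
#' @param trim_m Two-sided trim fraction on M-values (default 0.30).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (expr_scale(counts) != "counts") {
    abort("tmm_factors expects count-scale expression.")
  }
  lib <- colSums(counts)
  if (any(lib == 0)) abort("a sample has all-zero counts.")
  uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref_idx <- which.min(abs(uq - mean(uq)))
  r <- counts[, ref_idx]

  log_factors <- map_dbl(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]
    keep <- y > 0 & r > 0
    if (j == ref_idx || !any(keep)) return(0)
    M <- log2(y[keep] / r[keep])
    A <- 0.5 * log2(as.numeric(y[keep]) * r[keep])
    w <- 1 / ((lib[j] - y[keep]) / (lib[j] * y[keep]) +
                (lib[ref_idx] - r[keep]) / (lib[ref_idx] * r[keep]) + 1e-12)
    n <- length(M)
    lo_m <- quantile(M, trim_m); hi_m <- quantile(M, 1 - trim_m)
    lo_a <- quantile(A, trim_a); hi_a <- quantile(A, 1 - trim_a)
    kk <- M >= lo_m & M <= hi_m & A >= lo_a & A <= hi_a
    if (!any(kk)) kk <- rep(TRUE, n)
    sum(w[kk] * M[kk]) / sum(w[kk])
  })
  f <- 2^log_factors
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Select marker genes from a cell-type reference
#'
#' Per cell type, ranks genes by the specificity score (expression in that
#' type divided by the maximum expression across the other types) and keeps
#' the top `n_per_type`, ties broken by gene id. Genes with a score of at
#' most 1 are only used to fill up when fewer specific genes exist, with a
#' warning.
#'
#' @param reference A [cell_reference()].
#' @param n_per_type Markers to keep per cell type (default 100).
#' @return Tibble (`gene`, `cell_type`, `score`) — the marker map.
#' @export
select_markers <- function(reference, n_per_type = 100) {
  if (n_per_type < 1) abort("n_per_type must be at least 1.")
  R <- reference$values
  out <- map(seq_along(reference$cell_types), function(j) {
    own <- R[, j]
    other_max <- apply(R[, -j, drop = FALSE], 1, max)
    score <- own / pmax(other_max, .Machine$double.xmin)
    ord <- order(-score, rownames(R))
    take <- head(ord, n_per_type)
    if (sum(score > 1) < n_per_type) {
      warn(sprintf("cell type '%s': only %d genes with specificity > 1 (%d requested).",
                   reference$cell_types[j], sum(score > 1), n_per_type))
      take <- head(ord[score[ord] > 1], n_per_type)
    }
    tibble(gene = rownames(R)[take], cell_type = reference$cell_types[j],
           score = score[take])
  })
  bind_rows(out)
}

#' Digital-sorting proportion estimation
#'
#' Estimates per-sample cell-type fractions from cell-type-exclusive marker
#' genes. For each sample, the mean linear-scale expression of each type's
#' markers is proportional to that type's fraction; the per-type
#' proportionality constants are recovered by least squares on the
#' sum-to-one constraint (solve `M x ~ 1` for `x = 1/s > 0` across samples),
#' then proportions are `m * x`, negatives clipped to 0 and rows
#' renormalized to sum to 1.
#'
#' @param expr Expression matrix; log-scale input is de-logged with
#'   `2^x - 1` (mixing is linear in expression space).
#' @param markers Marker map from [select_markers()] (columns `gene`,
#'   `cell_type`).
#' @return A `proportion_estimate` tibble: `sample_id`, one fraction column
#'   per cell type, and `.resid` (per-sample residual of the sum-to-one
#'   fit).
#' @export
dsa_estimate <- function(expr, markers) {
  if (!all(markers$gene %in% rownames(expr))) {
    abort("all marker genes must be present in the expression matrix.")
  }
  E <- expr
  if (expr_scale(expr) %in% c("log2tpm", "normalized")) {
    E <- pmax(2^expr - 1, 0)
  }
  types <- unique(markers$cell_type)
  M <- vapply(types, function(tp) {
    g <- markers$gene[markers$cell_type == tp]
    colMeans(E[g, , drop = FALSE])
  }, numeric(ncol(E)))                           # samples x types

  MtM <- crossprod(M)
  if (rcond(MtM) < 1e-12) {
    abort("singular system: marker means are collinear across samples.")
  }
  x <- solve(MtM, colSums(M))                    # x = 1/s per type
  if (any(x <= 0)) {
    abort("singular or degenerate system: non-positive scale factors.")
  }
  P_raw <- sweep(M, 2, x, "*")
  resid <- abs(rowSums(P_raw) - 1)
  P <- pmax(P_raw, 0)
  P <- P / rowSums(P)

  out <- as_tibble(P, .name_repair = "minimal")
  names(out) <- types
  out <- bind_cols(tibble(sample_id = colnames(E)), out,
                   tibble(.resid = unname(resid)))
  structure(out, class = c("proportion_estimate", class(out)),
            cell_types = types)
}

#' Compare estimated proportions across sample groups
#'
#' Per cell type: a Kruskal-Wallis omnibus test across groups plus all
#' pairwise Wilcoxon rank-sum tests, the pairwise p-values BH-adjusted
#' within cell type.
#'
#' @param props A `proportion_estimate` from [dsa_estimate()].
#' @param groups Named vector (or vector aligned with `props$sample_id`) of
#'   group labels; every group needs at least 2 samples.
#' @return Tibble with `cell_type`, `test` (`"omnibus"` or `"pairwise"`),
#'   `group1`, `group2`, `statistic`, `p_value`, `adj_p`.
#' @export
compare_proportions <- function(props, groups) {
  if (!is.null(names(groups))) groups <- groups[props$sample_id]
  groups <- as.character(groups)
  if (any(table(groups) < 2)) abort("every group needs at least 2 samples.")
  lv <- sort(unique(groups))
  if (length(lv) < 2) abort("need at least 2 groups.")
  types <- attr(props, "cell_types")
  out <- map(types, function(tp) {
    v <- props[[tp]]
    omni <- kruskal_wallis(split(v, groups))
    rows <- tibble(cell_type = tp, test = "omnibus",
                   group1 = NA_character_, group2 = NA_character_,
                   statistic = omni$statistic, p_value = omni$p_value)
    pw <- list()
    for (i in seq_len(length(lv) - 1)) {
      for (j in (i + 1):length(lv)) {
        wt <- wilcoxon_rank_sum(v[groups == lv[i]], v[groups == lv[j]])
        pw[[length(pw) + 1]] <- tibble(
          cell_type = tp, test = "pairwise", group1 = lv[i], group2 = lv[j],
          statistic = wt$statistic, p_value = wt$p_value)
      }
    }
    pw <- bind_rows(pw)
    pw$adj_p <- bh_adjust(pw$p_value)
    rows$adj_p <- rows$p_value
    bind_rows(rows, pw)
  })
  bind_rows(out)
}

#' Expression variance explained by cell-type proportions
#'
#' Regresses every gene on the proportion matrix (intercept included; one
#' proportion column dropped since rows sum to 1) and summarizes the
#' per-gene R-squared as a variance-weighted (default) or unweighted mean —
#' the "how much of bulk expression variation do composition changes
#' explain" summary.
#'
#' @param expr Expression matrix.
#' @param props A `proportion_estimate` with the same samples.
#' @param weighted Weight the mean R-squared by gene variance (default
#'   `TRUE`).
#' @return A single fraction in `[0, 1]`.
#' @export
variance_explained <- function(expr, props, weighted = TRUE) {
  types <- attr(props, "cell_types")
  P <- as.matrix(props[, types])
  rownames(P) <- props$sample_id
  if (!all(colnames(expr) %in% rownames(P))) {
    abort("proportion estimates must cover every expression sample.")
  }
  P <- P[colnames(expr), , drop = FALSE]
  if (ncol(expr) < length(types) + 1) {
    abort("need more samples than cell types + 1.")
  }
  X <- cbind(1, P[, -1, drop = FALSE])           # drop one: rows sum to 1
  qrX <- qr(X)
  fitted <- X %*% qr.coef(qrX, t(expr))
  rss <- colSums((t(expr) - fitted)^2)
  tss <- colSums(scale(t(expr), scale = FALSE)^2)
  ok <- tss > 0
  r2 <- 1 - rss[ok] / tss[ok]
  w <- if (weighted) tss[ok] else rep(1, sum(ok))
  sum(w * r2) / sum(w)
}
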