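# Cross-cohort harmonization: log transform, parametric empirical-Bayes
# batch location/scale adjustment with covariate preservation, clamping plus
# quantile normalization, diagnosis-rule filtering, and removal of samples
# whose clustering conflicts with their clinical diagnosis.

#' Log2(x + 1) transform
#'
#' @param expr Expression matrix on a linear (TPM-like or counts) scale;
#'   values must be non-negative.
#' @return Transformed matrix with scale tag `log2tpm`.
#' @export
log_transform <- function(expr) {
  if (any(expr < 0)) abort("log transform requires non-negative values.")
  if (expr_scale(expr) %in% c("log2tpm", "normalized")) {
    abort("input is already on a log scale.")
  }
  out <- log2(expr + 1)
  attr(out, "scale") <- "log2tpm"
  out
}

#' Empirical-Bayes batch location/scale adjustment
#'
#' Parametric empirical-Bayes adjustment in the ComBat family, written for
#' this pipeline: per gene, fit expression on batch indicators plus
#' covariates; standardize against the batch-size-weighted grand mean and
#' pooled variance; shrink each batch's per-gene means and variances toward
#' across-gene moment-matched priors (normal on means, inverse-gamma on
#' variances; one pass, no iterative refinement); remove the shrunken batch
#' location/scale effects and re-add the covariate fit. Covariate effects
#' (e.g. a planted age slope) are preserved.
#'
#' @param expr Expression matrix (log scale).
#' @param meta Metadata tibble with `sample_id`, the batch column and
#'   covariates.
#' @param batch Name of the batch column (categorical, >= 2 samples per
#'   batch).
#' @param covariates Metadata columns whose effects must be preserved.
#' @return Adjusted matrix (scale tag `normalized`).
#' @export
batch_adjust <- function(expr, meta, batch = "batch",
                         covariates = character()) {
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  if (!batch %in% names(meta)) abort(sprintf("batch column '%s' missing.", batch))
  b <- factor(meta[[batch]])
  n_b <- table(b)
  if (any(n_b < 2)) {
    abort("every batch needs at least 2 samples (variance undefined).")
  }
  if (nlevels(b) == 1) return(expr)  # nothing to adjust

  n <- ncol(expr)
  batch_design <- model.matrix(~ 0 + b)
  X <- batch_design
  if (length(covariates)) {
    cov_df <- as.data.frame(meta[, covariates, drop = FALSE])
    Xc <- model.matrix(~ ., data = cov_df)[, -1, drop = FALSE]
    X <- cbind(batch_design, Xc)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("batch/covariate design is confounded.")
  B <- qr.coef(qrX, t(expr))                       # coef x genes
  nb <- nlevels(b)
  grand_mean <- crossprod(as.numeric(n_b) / n, B[seq_len(nb), , drop = FALSE])
  cov_fit <- if (ncol(X) > nb) {
    t(X[, -(seq_len(nb)), drop = FALSE] %*% B[-(seq_len(nb)), , drop = FALSE])
  } else {
    matrix(0, nrow(expr), n)
  }

  stand_mean <- matrix(grand_mean, nrow(expr), n) + cov_fit
  resid_full <- expr - t(X %*% B)
  var_pooled <- rowSums(resid_full^2) / n
  eps <- 1e-12
  sd_pooled <- sqrt(pmax(var_pooled, eps))
  Z <- (expr - stand_mean) / sd_pooled

  out <- Z
  gamma_hat <- matrix(NA_real_, nrow(expr), nb)
  delta_hat <- matrix(NA_real_, nrow(expr), nb)
  for (i in seq_len(nb)) {
    idx <- which(b == levels(b)[i])
    gamma_hat[, i] <- rowMeans(Z[, idx, drop = FALSE])
    delta_hat[, i] <- apply(Z[, idx, drop = FALSE], 1, var)
  }
  for (i in seq_len(nb)) {
    idx <- which(b == levels(b)[i])
    g <- gamma_hat[, i]
    d <- delta_hat[, i]
    # moment-matched priors across genes
    g_bar <- mean(g); t2 <- var(g)
    m <- mean(d); s2 <- var(d)
    g_star <- if (is.finite(t2) && t2 > eps) {
      (n_b[i] * t2 * g + d * g_bar) / (n_b[i] * t2 + d)
    } else {
      rep(g_bar, length(g))
    }
    if (is.finite(s2) && s2 > eps && m > eps) {
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      ssr <- rowSums((Z[, idx, drop = FALSE] - g_star)^2)
      d_star <- (b_prior + ssr / 2) / (n_b[i] / 2 + a_prior - 1)
    } else {
      d_star <- pmax(d, eps)
    }
    ratio <- sqrt(d_star)
    ratio[!is.finite(ratio) | ratio < 1e-9] <- 1
    out[, idx] <- (Z[, idx, drop = FALSE] - g_star) / ratio
  }

  adjusted <- out * sd_pooled + stand_mean
  attr(adjusted, "scale") <- "normalized"
  adjusted
}

#' Clamp negatives and quantile-normalize across samples
#'
#' Negative values are set to 0, then every sample's sorted values are
#' replaced by the across-sample mean of sorted values; tied values within a
#' sample receive the mean of the reference values over the sorted positions
#' they occupy (midrank averaging), so the result is invariant to sample and
#' row order.
#'
#' @param expr Expression matrix.
#' @return Normalized matrix (scale `normalized`); all columns share one
#'   sorted value multiset.
#' @export
clamp_quantile_normalize <- function(expr) {
  x <- pmax(expr, 0)
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(v) {
    s <- ref[rank(v, ties.method = "first")]
    stats::ave(s, factor(v), FUN = mean)
  })
  dimnames(out) <- dimnames(expr)
  attr(out, "scale") <- "normalized"
  out
}

#' Build a diagnosis rule
#'
#' A conjunction of field/operator/value clauses over metadata columns, e.g.
#' `diagnosis_rule(cdr = c("==", 0), braak = c("<=", 3), cerad = c("==", "NL"))`
#' for the neuropathologically normal rule, or `age = c(">", 70)`.
#'
#' @param ... Named clauses; each value is `c(op, value)` with op one of
#'   `==`, `!=`, `<`, `<=`, `>`, `>=`, `%in%`.
#' @return A `diagnosis_rule` tibble (`field`, `op`, `value`).
#' @export
diagnosis_rule <- function(...) {
  clauses <- list(...)
  ops <- c("==", "!=", "<", "<=", ">", ">=", "%in%")
  rows <- imap(clauses, function(cl, field) {
    if (length(cl) < 2 || !cl[[1]] %in% ops) {
      abort(sprintf("clause '%s' must be c(op, value) with a known operator.",
                    field))
    }
    tibble(field = field, op = cl[[1]], value = list(cl[-1]))
  })
  structure(bind_rows(rows), class = c("diagnosis_rule", "tbl_df", "tbl",
                                       "data.frame"))
}

#' Filter samples by a diagnosis rule
#'
#' @param meta Metadata tibble with `sample_id`.
#' @param rule A [diagnosis_rule()]; the empty rule keeps all samples.
#' @return Character vector of sample ids satisfying every clause.
#' @export
filter_by_diagnosis <- function(meta, rule) {
  keep <- rep(TRUE, nrow(meta))
  for (i in seq_len(nrow(rule))) {
    f <- rule$field[i]
    if (!f %in% names(meta)) abort(sprintf("rule field '%s' not in metadata.", f))
    v <- meta[[f]]
    val <- rule$value[[i]]
    target <- if (is.numeric(v)) as.numeric(unlist(val)) else
      as.character(unlist(val))
    ok <- switch(rule$op[i],
      "==" = v == target, "!=" = v != target,
      "<" = v < target, "<=" = v <= target,
      ">" = v > target, ">=" = v >= target,
      "%in%" = v %in% target)
    keep <- keep & !is.na(ok) & ok
  }
  meta$sample_id[keep]
}

#' Remove diagnosis-discordant ("mixed") samples
#'
#' Given a two-cluster labeling and a two-class diagnosis, assigns each
#' cluster its majority diagnosis and removes samples whose diagnosis
#' conflicts with their cluster's majority — the rule used to obtain a
#' cleanly separated case/control set before contrast analyses.
#'
#' @param cluster_labels Named vector of cluster labels.
#' @param diagnoses Named vector of diagnoses (two classes), same samples.
#' @return List with `retained` and `removed` sample-id vectors and a
#'   per-sample `table` tibble.
#' @export
remove_mixed_samples <- function(cluster_labels, diagnoses) {
  if (!setequal(names(cluster_labels), names(diagnoses))) {
    abort("cluster labels and diagnoses must cover the same samples.")
  }
  diagnoses <- diagnoses[names(cluster_labels)]
  if (length(unique(diagnoses)) != 2) {
    abort("exactly two diagnosis classes are required.")
  }
  tab <- tibble(sample_id = names(cluster_labels),
                cluster = as.character(cluster_labels),
                diagnosis = as.character(diagnoses))
  majority <- summarise(group_by(tab, .data$cluster), majority = {
    v <- sort(table(.data$diagnosis), decreasing = TRUE)
    if (length(v) > 1 && v[1] == v[2]) {
      abort(sprintf("cluster '%s' has an exact diagnosis tie; resolve manually.",
                    .data$cluster[1]))
    }
    names(v)[1]
  }, .groups = "drop")
  tab <- left_join(tab, majority, by = "cluster")
  tab$mixed <- tab$diagnosis != tab$majority
  list(retained = tab$sample_id[!tab$mixed],
       removed = tab$sample_id[tab$mixed],
       table = tab)
}
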