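# Directional gene signatures: covariate-adjusted per-gene linear models for
# age association or group contrasts, FDR thresholding with optional effect
# cut, consensus calling across signature collections, and the down-sampling
# robustness check. The design matrix is shared across genes, so all fits go
# through one QR decomposition.

#' Per-gene covariate-adjusted linear models
#'
#' Fits, for every gene, an ordinary-least-squares model of expression on a
#' target (a numeric covariate such as age, or a two-level group contrast)
#' plus adjustment covariates, and tests the target coefficient with a t
#' test; p-values are BH-adjusted across genes. Count-scale input is
#' transformed to `log2(CPM + 0.5)` first. Optionally, residual variances
#' are moderated by shrinking toward their pooled mean with prior weight
#' `moderate` (0 = plain OLS).
#'
#' @param expr Expression matrix (genes x samples; see [expr_matrix()]).
#' @param meta Sample metadata tibble with a `sample_id` column matching the
#'   expression columns.
#' @param target Metadata column to test. Numeric columns give a slope per
#'   unit; character/factor columns must have exactly two levels and give a
#'   log2 fold change (`contrast[1]` minus `contrast[2]`).
#' @param covariates Character vector of metadata columns to adjust for.
#' @param contrast For factor targets, length-2 character vector
#'   `c(test_level, reference_level)`; defaults to the reverse-sorted levels.
#' @param moderate Non-negative prior weight (pseudo-degrees of freedom) for
#'   pooled-variance moderation; 0 disables it.
#' @return A `gene_stats` tibble: `gene`, `estimate`, `se`, `statistic`,
#'   `p_value`, `fdr`, with the tested universe and model info as attributes.
#' @export
fit_gene_models <- function(expr, meta, target = "age",
                            covariates = character(), contrast = NULL,
                            moderate = 0) {
  if (!all(colnames(expr) %in% meta$sample_id)) {
    abort("every expression sample needs a metadata row.")
  }
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  missing_cols <- setdiff(c(target, covariates), names(meta))
  if (length(missing_cols)) {
    abort(paste0("metadata columns not found: ",
                 paste(missing_cols, collapse = ", ")))
  }

  Y <- expr
  if (expr_scale(expr) == "counts") {
    libs <- colSums(Y)
    Y <- log2(sweep(Y, 2, libs, "/") * 1e6 + 0.5)
  }

  tv <- meta[[target]]
  if (is.numeric(tv)) {
    tcol <- tv
    target_name <- target
  } else {
    tv <- as.character(tv)
    lev <- sort(unique(tv))
    if (length(lev) != 2) abort("group targets must have exactly two levels.")
    if (is.null(contrast)) contrast <- rev(lev)
    if (!setequal(contrast, lev)) abort("contrast levels must match the data.")
    tcol <- as.numeric(tv == contrast[1])
    target_name <- paste0(target, ":", contrast[1], "_vs_", contrast[2])
  }

  df_design <- data.frame(..target = tcol)
  for (cv in covariates) df_design[[cv]] <- meta[[cv]]
  X <- model.matrix(~ ., data = df_design)

  if (nrow(X) < ncol(X) + 2) {
    abort("need at least (number of coefficients + 2) samples.")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design is rank deficient; collinear columns: ",
                 paste(dropped, collapse = ", ")))
  }

  B <- qr.coef(qrX, t(Y))                       # p x genes
  resid <- t(Y) - X %*% B
  df_resid <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df_resid

  if (moderate > 0) {
    s2_prior <- mean(sigma2)
    sigma2 <- (moderate * s2_prior + df_resid * sigma2) / (moderate + df_resid)
    df_t <- df_resid + moderate
  } else {
    df_t <- df_resid
  }

  XtX_inv <- chol2inv(qr.R(qrX))
  j <- which(colnames(X) == "..target")
  se <- sqrt(sigma2 * XtX_inv[j, j])
  est <- B[j, ]
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  p <- 2 * pt(abs(tstat), df = df_t, lower.tail = FALSE)

  out <- tibble(gene = rownames(expr), estimate = unname(est),
                se = unname(se), statistic = unname(tstat),
                p_value = unname(p), fdr = bh_adjust(unname(p)))
  structure(out, class = c("gene_stats", class(out)),
            target = target_name, n_samples = nrow(X), df = df_t,
            universe = rownames(expr))
}

#' Derive a directional signature from per-gene statistics
#'
#' Genes with adjusted p at or below `fdr_cut` enter the up or down set by
#' the sign of their effect; if `effect_cut` is given, only genes with
#' `|effect| > effect_cut` (strict) are kept. The universe is the full set of
#' tested genes.
#'
#' @param stats A `gene_stats` tibble from [fit_gene_models()].
#' @param fdr_cut Adjusted-p threshold (default 0.05).
#' @param effect_cut Optional strict absolute-effect threshold (e.g. 1 for
#'   `|log2FC| > 1`).
#' @param id Signature id; defaults to the fitted target name.
#' @return A [gene_signature()].
#' @export
derive_signature <- function(stats, fdr_cut = 0.05, effect_cut = NULL,
                             id = NULL) {
  if (!all(c("gene", "estimate", "fdr") %in% names(stats))) {
    abort("`stats` must carry gene, estimate and fdr columns.")
  }
  keep <- stats$fdr <= fdr_cut
  if (!is.null(effect_cut)) keep <- keep & abs(stats$estimate) > effect_cut
  if (is.null(id)) id <- attr(stats, "target") %||% "signature"
  universe <- attr(stats, "universe") %||% stats$gene
  gene_signature(
    id = id,
    up = stats$gene[keep & stats$estimate > 0],
    down = stats$gene[keep & stats$estimate < 0],
    universe = universe,
    provenance = list(fdr_cut = fdr_cut, effect_cut = effect_cut,
                      n_samples = attr(stats, "n_samples")))
}

#' Consensus signature across a collection
#'
#' A gene enters the consensus up set iff it is in the up set of at least
#' `min_lists` signatures and (when `require_no_conflict`) in the down set of
#' none; symmetrically for down. The shipped thresholds in the pipeline
#' configs follow the "more than 4 out of 19" (so `min_lists = 5`) and
#' "at least 9 out of 32" (`min_lists = 9`) rules.
#'
#' @param signatures List of [gene_signature()] objects.
#' @param min_lists Minimum number of supporting lists.
#' @param require_no_conflict Drop genes that appear in the opposite
#'   direction in any list (default `TRUE`).
#' @param id Consensus signature id.
#' @return A [gene_signature()]; universe is the union of input universes.
#' @export
consensus_signature <- function(signatures, min_lists,
                                require_no_conflict = TRUE,
                                id = "consensus") {
  if (min_lists > length(signatures)) {
    abort("min_lists exceeds the number of signatures.")
  }
  up_counts <- table(unlist(lapply(signatures, `[[`, "up")))
  dn_counts <- table(unlist(lapply(signatures, `[[`, "down")))
  up_genes <- names(up_counts)[up_counts >= min_lists]
  dn_genes <- names(dn_counts)[dn_counts >= min_lists]
  if (require_no_conflict) {
    up_genes <- setdiff(up_genes, names(dn_counts))
    dn_genes <- setdiff(dn_genes, names(up_counts))
  } else {
    both <- intersect(up_genes, dn_genes)   # keep the majority direction
    if (length(both)) {
      keep_up <- up_counts[both] > dn_counts[both]
      up_genes <- setdiff(up_genes, both[!keep_up])
      dn_genes <- setdiff(dn_genes, both[keep_up])
    }
  }
  universe <- unique(unlist(lapply(signatures, `[[`, "universe")))
  gene_signature(id = id, up = sort(up_genes), down = sort(dn_genes),
                 universe = universe,
                 provenance = list(min_lists = min_lists,
                                   n_lists = length(signatures),
                                   require_no_conflict = require_no_conflict))
}

#' Down-sampling robustness of a signature's size
#'
#' Repeatedly subsamples `n_sub` samples without replacement, refits the
#' per-gene models and rederives the signature, reporting the distribution of
#' signature sizes (up + down) across replicates. Used to compare regions
#' with unequal sample sizes on equal footing.
#'
#' @inheritParams fit_gene_models
#' @param n_sub Subsample size (must allow the model fit).
#' @param n_reps Number of replicates.
#' @param fdr_cut Adjusted-p threshold passed to [derive_signature()].
#' @param seed Integer seed; each replicate uses a named substream.
#' @return A `downsample_result` tibble (`rep`, `n_genes`) with `mean` and
#'   `sd` attributes; see [glance.downsample_result()].
#' @export
downsample_signature_count <- function(expr, meta, target = "age",
                                       covariates = character(),
                                       n_sub, n_reps = 20, fdr_cut = 0.05,
                                       seed = 1L) {
  if (n_sub > ncol(expr)) abort("n_sub exceeds the number of samples.")
  counts <- map_dbl(seq_len(n_reps), function(r) {
    idx <- with_substream(seed, paste0("downsample", r),
                          sample(ncol(expr), n_sub))
    sub_expr <- expr[, idx, drop = FALSE]
    attr(sub_expr, "scale") <- expr_scale(expr)
    st <- fit_gene_models(sub_expr, meta, target = target,
                          covariates = covariates)
    sig <- derive_signature(st, fdr_cut = fdr_cut)
    length(sig$up) + length(sig$down)
  })
  out <- tibble(rep = seq_len(n_reps), n_genes = counts)
  structure(out, class = c("downsample_result", class(out)),
            mean = mean(counts), sd = if (n_reps > 1) sd(counts) else 0,
            n_sub = n_sub)
}

#' @rdname downsample_signature_count
#' @param x A `downsample_result`.
#' @param ... Unused.
#' @export
glance.downsample_result <- function(x, ...) {
  tibble(mean = attr(x, "mean"), sd = attr(x, "sd"),
         n_sub = attr(x, "n_sub"), n_reps = nrow(x))
}
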