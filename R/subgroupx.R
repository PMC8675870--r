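# Aging-subgroup discovery: variable-gene selection, Ward.D2 hierarchical
# clustering of samples, clustering concordance across gene subsets, and
# leave-one-in projection of external samples onto reference subgroups.

#' Residualize expression on covariates
#'
#' Removes linear covariate effects gene-wise (OLS residuals plus the gene
#' mean), so that clustering and deconvolution can operate on
#' covariate-adjusted expression.
#'
#' @param expr Expression matrix.
#' @param meta Metadata tibble with `sample_id` matching the columns.
#' @param covariates Metadata columns to residualize on.
#' @return Adjusted expression matrix (same scale tag).
#' @export
residualize_covariates <- function(expr, meta, covariates) {
  if (length(covariates) == 0) return(expr)
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  df <- as.data.frame(meta[, covariates, drop = FALSE])
  X <- model.matrix(~ ., data = df)
  qrX <- qr(X)
  fitted <- t(X %*% qr.coef(qrX, t(expr)))
  out <- expr - fitted + rowMeans(expr)
  attr(out, "scale") <- expr_scale(expr)
  out
}

#' Select the most variable genes
#'
#' Genes ranked by across-sample variance (descending), ties broken by gene
#' id lexicographically so the selection is deterministic.
#'
#' @param expr Expression matrix.
#' @param k Number of genes to return (`0 < k <= n_genes`).
#' @return Character vector of `k` gene ids.
#' @export
select_variable_genes <- function(expr, k) {
  if (k <= 0) abort("k must be positive.")
  if (k > nrow(expr)) abort("k exceeds the number of genes.")
  v <- apply(expr, 1, var)
  ord <- order(-v, rownames(expr))
  rownames(expr)[ord][seq_len(k)]
}

#' Ward.D2 hierarchical clustering of samples
#'
#' Agglomerative clustering of sample columns on Euclidean distances with the
#' Ward.D2 criterion (heights on the distance scale), cut into `n_clusters`.
#' Samples are ordered by id before clustering so the result does not depend
#' on input column order.
#'
#' @param expr Expression matrix (optionally pre-subset to a clustering gene
#'   set, e.g. from [select_variable_genes()]).
#' @param n_clusters Number of clusters to cut (`2 <= n_clusters <=
#'   n_samples`).
#' @param genes Optional gene ids to cluster on (default: all rows).
#' @return A `ward_clustering` object: the `hclust` tree, integer `labels`
#'   named by sample, the gene set used and parameters.
#' @export
ward_cluster <- function(expr, n_clusters, genes = NULL) {
  if (anyDuplicated(colnames(expr))) abort("duplicate sample ids.")
  if (ncol(expr) < 2) abort("need at least 2 samples.")
  if (n_clusters > ncol(expr) || n_clusters < 1) {
    abort("n_clusters must lie between 1 and the number of samples.")
  }
  if (!is.null(genes)) expr <- expr[genes, , drop = FALSE]
  expr <- expr[, order(colnames(expr)), drop = FALSE]
  d <- dist(t(expr), method = "euclidean")
  tree <- hclust(d, method = "ward.D2")
  labels <- cutree(tree, k = n_clusters)
  structure(list(tree = tree, labels = labels,
                 genes = rownames(expr), n_clusters = n_clusters),
            class = "ward_clustering")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> %d samples, %d clusters (sizes: %s)\n",
              length(x$labels), x$n_clusters,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Clustering concordance across gene-subset sizes
#'
#' Adjusted Rand index between the clustering on each top-k variable-gene
#' subset and the clustering on all genes — the check used to justify
#' clustering on the top 5,000 variable genes (ARI > 0.9).
#'
#' @param expr Expression matrix.
#' @param gene_subset_sizes Integer vector of top-k sizes.
#' @param n_clusters Number of clusters for every run.
#' @return Tibble with `n_genes` and `ari`.
#' @export
clustering_concordance <- function(expr, gene_subset_sizes, n_clusters) {
  full <- ward_cluster(expr, n_clusters)
  tibble(
    n_genes = as.integer(gene_subset_sizes),
    ari = map_dbl(gene_subset_sizes, function(k) {
      sub <- ward_cluster(expr, n_clusters,
                          genes = select_variable_genes(expr, k))
      adjusted_rand_index(sub$labels[names(full$labels)], full$labels)
    }))
}

#' Leave-one-in projection of external samples onto reference subgroups
#'
#' Each external sample is appended on its own to the reference matrix, the
#' combined samples are re-clustered with [ward_cluster()] at the reference
#' number of subgroups, clusters are mapped to reference subgroup ids by the
#' majority of their original members, and the sample receives the label of
#' the cluster it lands in. A cluster whose original members have no strict
#' majority yields `"ambiguous"`.
#'
#' @param ref_expr Reference expression matrix (e.g. already restricted to
#'   the clustering gene set).
#' @param ref_labels Named vector of reference subgroup labels (names =
#'   reference sample ids).
#' @param external_expr External expression matrix sharing the reference
#'   gene space.
#' @param genes Optional gene ids to cluster on.
#' @return Tibble: `sample_id`, `assigned`, `majority_frac` (the mapped
#'   cluster's majority fraction among original members).
#' @export
assign_external_samples <- function(ref_expr, ref_labels, external_expr,
                                    genes = NULL) {
  external_expr <- check_same_genes(ref_expr, external_expr)
  if (!setequal(names(ref_labels), colnames(ref_expr))) {
    abort("ref_labels must be named by the reference sample ids.")
  }
  k <- length(unique(ref_labels))
  if (!is.null(genes)) {
    ref_expr <- ref_expr[genes, , drop = FALSE]
    external_expr <- external_expr[genes, , drop = FALSE]
  }
  res <- map(colnames(external_expr), function(sid) {
    combined <- cbind(ref_expr, external_expr[, sid, drop = FALSE])
    wc <- ward_cluster(combined, n_clusters = k)
    cl <- wc$labels
    new_cluster <- cl[[sid]]
    members <- names(cl)[cl == new_cluster & names(cl) != sid]
    if (length(members) == 0) {
      return(tibble(sample_id = sid, assigned = "ambiguous",
                    majority_frac = 0))
    }
    votes <- sort(table(ref_labels[members]), decreasing = TRUE)
    tied <- sum(votes == votes[1]) > 1
    tibble(sample_id = sid,
           assigned = if (tied) "ambiguous" else names(votes)[1],
           majority_frac = as.numeric(votes[1]) / length(members))
  })
  bind_rows(res)
}
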