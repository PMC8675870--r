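# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gene-signature into a long tibble
#' @param x A [gene_signature()].
#' @param ... Unused.
#' @return Tibble with `signature`, `gene`, `direction`.
#' @export
tidy.gene_signature <- function(x, ...) {
  tibble(signature = x$id,
         gene = c(x$up, x$down),
         direction = rep(c("UP", "DN"), c(length(x$up), length(x$down))))
}

#' @rdname tidy.gene_signature
#' @export
glance.gene_signature <- function(x, ...) {
  tibble(signature = x$id, n_up = length(x$up), n_down = length(x$down),
         universe = length(x$universe))
}

#' Summarize per-gene model statistics
#' @param x A `gene_stats` tibble from [fit_gene_models()].
#' @param fdr_cut Threshold used for the significant-gene count.
#' @param ... Unused.
#' @return One-row tibble: target, samples, genes tested, genes passing.
#' @export
glance.gene_stats <- function(x, fdr_cut = 0.05, ...) {
  tibble(target = attr(x, "target"), n_samples = attr(x, "n_samples"),
         n_genes = nrow(x), n_significant = sum(x$fdr <= fdr_cut),
         fdr_cut = fdr_cut)
}

#' Tidy a clustering result
#' @param x A `ward_clustering` from [ward_cluster()].
#' @param ... Unused.
#' @return Tibble with `sample_id` and `cluster`.
#' @export
tidy.ward_clustering <- function(x, ...) {
  tibble(sample_id = names(x$labels), cluster = unname(x$labels))
}

#' @rdname tidy.ward_clustering
#' @export
glance.ward_clustering <- function(x, ...) {
  tibble(n_samples = length(x$labels), n_clusters = x$n_clusters,
         n_genes = length(x$genes), max_height = max(x$tree$height))
}

#' Tidy estimated cell-type proportions into long format
#' @param x A `proportion_estimate` from [dsa_estimate()].
#' @param ... Unused.
#' @return Tibble with `sample_id`, `cell_type`, `proportion`.
#' @export
tidy.proportion_estimate <- function(x, ...) {
  types <- attr(x, "cell_types")
  tidyr::pivot_longer(x[, c("sample_id", types)], -"sample_id",
                      names_to = "cell_type", values_to = "proportion")
}

#' Volcano plot of per-gene statistics
#' @param object A `gene_stats` tibble.
#' @param fdr_cut Highlighting threshold.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_stats <- function(object, fdr_cut = 0.05, ...) {
  df <- mutate(object, significant = .data$fdr <= fdr_cut)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "effect estimate", y = "-log10 p",
                  colour = sprintf("FDR ≤ %g", fdr_cut)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a directional overlap matrix
#'
#' Tiles show the overlap counts; fill encodes `-log10(adjusted p)`,
#' faceted by direction pair — the usual rows-by-columns enrichment grid.
#'
#' @param object An `overlap_matrix` from [build_overlap_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  df <- mutate(object, evidence = -log10(pmax(.data$adj_p, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_id, y = .data$row_id,
                                   fill = .data$evidence)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$k), size = 3) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10 adj p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Boxplots of estimated proportions by group
#' @param object A `proportion_estimate`.
#' @param groups Optional named group vector (names = sample ids).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.proportion_estimate <- function(object, groups = NULL, ...) {
  df <- tidy.proportion_estimate(object)
  if (!is.null(groups)) {
    df$group <- as.character(groups[df$sample_id])
  } else {
    df$group <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$proportion,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "estimated proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Dendrogram of a Ward clustering
#' @param object A `ward_clustering`.
#' @param ... Unused.
#' @return A ggplot drawn from the merge history.
#' @export
autoplot.ward_clustering <- function(object, ...) {
  seg <- dendrogram_segments(object$tree)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(object$tree$labels),
      labels = object$tree$labels[object$tree$order]) +
    ggplot2::labs(x = NULL, y = "height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       size = 6))
}

# hclust merge table -> line segments for plotting
dendrogram_segments <- function(tree) {
  pos <- match(seq_along(tree$labels), tree$order)  # leaf x-positions
  node_x <- numeric(nrow(tree$merge))
  node_y <- tree$height
  segs <- list()
  leaf <- function(i) list(x = pos[-i], y = 0)
  node <- function(i) list(x = node_x[i], y = node_y[i])
  for (i in seq_len(nrow(tree$merge))) {
    a <- tree$merge[i, 1]
    b <- tree$merge[i, 2]
    pa <- if (a < 0) leaf(a) else node(a)
    pb <- if (b < 0) leaf(b) else node(b)
    node_x[i] <- (pa$x + pb$x) / 2
    segs[[length(segs) + 1]] <- tibble(
      x = c(pa$x, pb$x, pa$x), y = c(pa$y, pb$y, node_y[i]),
      xend = c(pa$x, pb$x, pb$x), yend = c(node_y[i], node_y[i], node_y[i]))
  }
  bind_rows(segs)
}
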