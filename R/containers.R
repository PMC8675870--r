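# Core containers shared across the pipeline: the expression matrix (a plain
# numeric matrix, genes x samples, carrying a scale tag), directional gene
# signatures, and the cell-type reference used for deconvolution.

#' Construct an expression matrix
#'
#' Expression data are stored as a base numeric matrix with genes as rows and
#' samples as columns, plus a `scale` attribute recording what the values are:
#' raw counts, TPM-like linear abundances, `log2(TPM + 1)`, or `normalized`
#' (post batch-adjustment / quantile normalization, still log-like).
#'
#' @param values Numeric matrix, genes as rows (unique rownames) and samples
#'   as columns (unique colnames). All values must be finite.
#' @param scale One of `"counts"`, `"tpm"`, `"log2tpm"`, `"normalized"`.
#' @return The validated matrix with a `scale` attribute.
#' @export
expr_matrix <- function(values, scale = c("log2tpm", "counts", "tpm", "normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)) ||
      any(rownames(values) == "")) {
    abort("gene ids (rownames) must be present and unique.")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)) ||
      any(colnames(values) == "")) {
    abort("sample ids (colnames) must be present and unique.")
  }
  if (!all(is.finite(values))) abort("expression values must be finite.")
  attr(values, "scale") <- scale
  values
}

#' Get or set the scale tag of an expression matrix
#' @param x Expression matrix.
#' @return The scale tag (character).
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "log2tpm" else s
}

`expr_scale<-` <- function(x, value) {
  attr(x, "scale") <- value
  x
}

#' Construct a directional gene signature
#'
#' A signature is a pair of disjoint up- and down-regulated gene sets together
#' with the universe of genes that were tested to derive it (needed for
#' overlap enrichment) and free-form provenance.
#'
#' @param id Signature identifier, e.g. `"G_HIPP"`.
#' @param up,down Character vectors of gene ids; must be disjoint and
#'   contained in `universe`.
#' @param universe Character vector of all tested gene ids.
#' @param provenance Optional named list (cohort, region, thresholds, ...).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(id, up, down, universe, provenance = list()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  universe <- unique(as.character(universe))
  if (length(intersect(up, down)) > 0) {
    abort("up and down sets must be disjoint.")
  }
  if (!all(up %in% universe) || !all(down %in% universe)) {
    abort("up and down sets must be subsets of the universe.")
  }
  structure(
    list(id = as.character(id), up = up, down = down,
         universe = universe, provenance = provenance),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d up / %d down (universe %d)\n",
              x$id, length(x$up), length(x$down), length(x$universe)))
  invisible(x)
}

#' Construct a cell-type reference for deconvolution
#'
#' @param values Numeric matrix, genes x cell types, linear-scale expression.
#' @param markers Tibble with columns `gene` and `cell_type` flagging each
#'   marker gene for exactly one cell type; may be empty (markers can be
#'   selected later with [select_markers()]).
#' @return An object of class `cell_reference`.
#' @export
cell_reference <- function(values, markers = NULL) {
  if (!is.matrix(values) || ncol(values) < 2) {
    abort("reference must be a matrix with at least 2 cell-type columns.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("reference needs gene rownames and cell-type colnames.")
  }
  if (is.null(markers)) {
    markers <- tibble(gene = character(), cell_type = character())
  }
  if (anyDuplicated(markers$gene)) {
    abort("each marker gene must be flagged for exactly one cell type.")
  }
  if (!all(markers$cell_type %in% colnames(values))) {
    abort("marker cell types must match reference columns.")
  }
  structure(list(values = values, cell_types = colnames(values),
                 markers = as_tibble(markers)),
            class = "cell_reference")
}

#' @export
print.cell_reference <- function(x, ...) {
  cat(sprintf("<cell_reference> %d genes x %d cell types (%d markers flagged)\n",
              nrow(x$values), length(x$cell_types), nrow(x$markers)))
  invisible(x)
}

# internal: check that two expression matrices share a gene space
check_same_genes <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) {
    if (setequal(rownames(a), rownames(b))) {
      return(b[rownames(a), , drop = FALSE])
    }
    abort("gene spaces differ between the two expression matrices.")
  }
  b
}
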