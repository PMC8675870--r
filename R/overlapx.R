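# Directional overlap enrichment between signature collections, and the
# subgroup -> AD similarity ordering built from signed enrichment evidence.

direction_pairs <- c("UP/UP", "DN/DN", "UP/DN", "DN/UP")

sig_set <- function(sig, dir) if (dir == "UP") sig$up else sig$down

resolve_universe <- function(row_sig, col_sig, universe_policy, universe) {
  switch(universe_policy,
    intersection = intersect(row_sig$universe, col_sig$universe),
    union = union(row_sig$universe, col_sig$universe),
    fixed = universe,
    abort("unknown universe policy."))
}

#' Directional overlap-enrichment matrix between two signature collections
#'
#' For every row signature x column signature x direction pair (UP/UP,
#' DN/DN, UP/DN, DN/UP), counts the shared genes and tests the overlap with
#' the one-sided hypergeometric upper tail, then BH-adjusts across cells.
#' The universe defaults to the intersection of the two signatures' tested
#' gene universes.
#'
#' @param rows,cols Lists of [gene_signature()] objects.
#' @param universe_policy `"intersection"` (default), `"union"`, or
#'   `"fixed"` (then give `universe`, a character vector of gene ids).
#' @param universe Gene ids used when `universe_policy = "fixed"`.
#' @param adjust Adjustment scope: `"matrix"` (all cells jointly, default) or
#'   `"row"` (within each row signature).
#' @return An `overlap_matrix` tibble with one row per cell: `row_id`,
#'   `col_id`, `direction`, `k`, `n1`, `n2`, `N`, `p_value`, `adj_p`.
#' @export
build_overlap_matrix <- function(rows, cols,
                                 universe_policy = c("intersection", "union",
                                                     "fixed"),
                                 universe = NULL,
                                 adjust = c("matrix", "row")) {
  universe_policy <- match.arg(universe_policy)
  adjust <- match.arg(adjust)
  if (length(rows) == 0 || length(cols) == 0) {
    abort("both signature collections must be non-empty.")
  }
  if (universe_policy == "fixed" && is.null(universe)) {
    abort("universe_policy = 'fixed' requires `universe`.")
  }

  cells <- list()
  for (rs in rows) {
    for (cs_ in cols) {
      U <- resolve_universe(rs, cs_, universe_policy, universe)
      if (length(U) == 0) {
        abort(sprintf("empty universe for %s x %s under the %s policy.",
                      rs$id, cs_$id, universe_policy))
      }
      for (dp in direction_pairs) {
        d <- strsplit(dp, "/", fixed = TRUE)[[1]]
        set1 <- intersect(sig_set(rs, d[1]), U)
        set2 <- intersect(sig_set(cs_, d[2]), U)
        k <- length(intersect(set1, set2))
        res <- hypergeom_tail(k, length(set1), length(set2), length(U))
        cells[[length(cells) + 1L]] <- tibble(
          row_id = rs$id, col_id = cs_$id, direction = dp,
          k = k, n1 = length(set1), n2 = length(set2), N = length(U),
          p_value = res$p_value)
      }
    }
  }
  out <- bind_rows(cells)
  out <- arrange(out, .data$row_id, .data$col_id, .data$direction)
  out$adj_p <- if (adjust == "matrix") {
    bh_adjust(out$p_value)
  } else {
    stats::ave(out$p_value, out$row_id,
               FUN = function(p) p.adjust(p, "BH"))
  }
  structure(out, class = c("overlap_matrix", class(out)),
            universe_policy = universe_policy, adjust = adjust)
}

#' Order subgroups by similarity to AD signatures
#'
#' Operationalizes the "which subgroup looks most like AD" judgement as a
#' signed enrichment score: for each subgroup's DEG signature against the
#' baseline subgroup, score = sum of `-log10(adjusted p)` over
#' direction-concordant overlap cells (UP/UP, DN/DN) minus the same sum over
#' discordant cells (UP/DN, DN/UP), summed over all AD signatures. The
#' baseline subgroup scores 0 by construction; subgroups are ranked by
#' decreasing score, ties broken lexicographically and flagged.
#'
#' @param subgroup_degs Named list of [gene_signature()] objects, one per
#'   non-baseline subgroup, named `"<subgroup>vs<baseline>"` (e.g. `"BvsA"`).
#' @param ad_sigs List of AD [gene_signature()] objects.
#' @param baseline Baseline subgroup id (e.g. `"A"`).
#' @inheritParams build_overlap_matrix
#' @return A `similarity_ordering` tibble (`subgroup`, `score`, `rank`,
#'   `tie`), with the per-cell score components as the `components`
#'   attribute.
#' @export
order_by_ad_similarity <- function(subgroup_degs, ad_sigs, baseline = "A",
                                   universe_policy = "intersection",
                                   universe = NULL) {
  nms <- names(subgroup_degs)
  if (is.null(nms) || !all(grepl("vs", nms, fixed = TRUE))) {
    abort("subgroup_degs must be named like 'BvsA'.")
  }
  parts <- strsplit(nms, "vs", fixed = TRUE)
  subgroups <- map_chr(parts, 1)
  bases <- map_chr(parts, 2)
  if (!all(bases == baseline)) {
    abort(sprintf("every DEG signature must contrast against the baseline '%s'.",
                  baseline))
  }

  degs <- subgroup_degs
  for (i in seq_along(degs)) degs[[i]]$id <- subgroups[i]
  om <- build_overlap_matrix(degs, ad_sigs,
                             universe_policy = universe_policy,
                             universe = universe, adjust = "matrix")
  p_floor <- .Machine$double.xmin
  comp <- mutate(om,
    concordant = .data$direction %in% c("UP/UP", "DN/DN"),
    evidence = -log10(pmax(.data$adj_p, p_floor)),
    signed = ifelse(.data$concordant, .data$evidence, -.data$evidence))
  scores <- summarise(group_by(comp, subgroup = .data$row_id),
                      score = sum(.data$signed), .groups = "drop")
  scores <- bind_rows(scores, tibble(subgroup = baseline, score = 0))
  scores <- arrange(scores, desc(.data$score), .data$subgroup)
  scores$rank <- seq_len(nrow(scores))
  scores$tie <- duplicated(round(scores$score, 9)) |
    duplicated(round(scores$score, 9), fromLast = TRUE)
  structure(scores, class = c("similarity_ordering", class(scores)),
            components = comp, baseline = baseline)
}

#' @export
print.similarity_ordering <- function(x, ...) {
  cat("<similarity_ordering> most to least AD-similar:",
      paste(x$subgroup, collapse = " > "), "\n")
  NextMethod()
}
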