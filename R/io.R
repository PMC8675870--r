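# Plain-text readers/writers for the pipeline's artifacts: expression and
# metadata TSVs, two-column signature TSVs, GMT signature collections, and
# YAML simulation configs.

#' Write / read an expression matrix as TSV
#'
#' Genes as rows; the first column (`gene`) holds gene ids, the header row
#' the sample ids. The scale tag is stored in a `# scale:` comment line.
#'
#' @param expr Expression matrix.
#' @param path Output path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns the matrix with its scale tag.
#' @export
write_expression_tsv <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale: %s", expr_scale(expr)), con)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1)
  scale <- if (grepl("^# scale:", first)) {
    trimws(sub("^# scale:", "", first))
  } else "log2tpm"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m, scale)
}

#' Write / read sample metadata as TSV
#' @param meta Metadata tibble.
#' @param path File path.
#' @export
write_metadata_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Write / read a directional signature as two-column TSV
#'
#' Columns `gene` and `direction` (`UP`/`DN`); the universe and id are kept
#' in comment lines so a round trip preserves them.
#'
#' @param sig A [gene_signature()].
#' @param path File path.
#' @export
write_signature_tsv <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# id: %s", sig$id),
               sprintf("# universe: %s", paste(sig$universe, collapse = ","))),
             con)
  df <- data.frame(
    gene = c(sig$up, sig$down),
    direction = rep(c("UP", "DN"), c(length(sig$up), length(sig$down))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  id <- trimws(sub("^# id:", "", hdr[grepl("^# id:", hdr)]))
  uni <- strsplit(trimws(sub("^# universe:", "",
                             hdr[grepl("^# universe:", hdr)])), ",")[[1]]
  df <- utils::read.delim(path, comment.char = "#")
  up <- df$gene[df$direction == "UP"]
  dn <- df$gene[df$direction == "DN"]
  if (length(uni) == 0) uni <- c(up, dn)
  gene_signature(id = if (length(id)) id else "signature",
                 up = up, down = dn, universe = uni)
}

#' Write / read signature collections as GMT
#'
#' One up-set and one down-set record per signature, with id suffixes
#' `_UP` / `_DN`; the description field carries the universe size.
#'
#' @param signatures List of [gene_signature()] objects.
#' @param path File path.
#' @export
write_signatures_gmt <- function(signatures, path) {
  lines <- unlist(lapply(signatures, function(s) {
    c(paste(c(paste0(s$id, "_UP"),
              sprintf("universe=%d", length(s$universe)), s$up),
            collapse = "\t"),
      paste(c(paste0(s$id, "_DN"),
              sprintf("universe=%d", length(s$universe)), s$down),
            collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_signatures_gmt
#' @param universe Gene universe to attach to every signature read back (GMT
#'   does not store the gene-level universe); defaults to the union of all
#'   sets in the file.
#' @export
read_signatures_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- map_chr(parts, 1)
  base <- unique(sub("_(UP|DN)$", "", ids))
  all_genes <- unique(unlist(lapply(parts, function(p) p[-(1:2)])))
  if (is.null(universe)) universe <- all_genes
  lapply(setNames(base, base), function(b) {
    up <- dn <- character()
    iu <- match(paste0(b, "_UP"), ids)
    idn <- match(paste0(b, "_DN"), ids)
    if (!is.na(iu)) up <- parts[[iu]][-(1:2)]
    if (!is.na(idn)) dn <- parts[[idn]][-(1:2)]
    gene_signature(b, up, dn, union(universe, c(up, dn)))
  })
}

#' Read a simulation config from YAML
#'
#' Top-level keys are the arguments of [sim_config()]; nested maps override
#' individual entries of `covariate_spec`, `subgroup_spec`, `ad_spec` and
#' `mixture_spec`.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown sim config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, raw)
}
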