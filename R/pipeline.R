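# Pipeline orchestration: run the full analysis (simulate or ingest ->
# signatures -> overlap -> subgroups -> harmonize -> project -> deconvolve ->
# report) from one config, each stage reading and writing plain-text
# artifacts in the output directory so stages can be re-run individually.

pipeline_stages <- c("simulate", "signatures", "subgroups", "overlap",
                     "harmonize", "project", "deconvolve", "report")

#' Default pipeline configuration
#'
#' Returns the fully populated configuration list the pipeline runs from; a
#' user config (YAML) overrides any subset of it. The synthetic reference
#' cohort carries three aging subgroups; the external (AD case/control)
#' cohort shares the same gene space; the mixture cohort has three sample
#' groups with shifted cell-type composition (neuron loss and microglia gain
#' in the non-baseline groups).
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L, outdir = "agingtx_out") {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = TRUE,
    sim = list(
      n_genes = 6000, n_samples = 56, n_age_genes = 100,
      mixture_spec = list(
        alpha = list(c(0.40, 0.20, 0.10, 0.10, 0.20) * 50,
                     c(0.25, 0.25, 0.10, 0.15, 0.25) * 50,
                     c(0.33, 0.22, 0.10, 0.12, 0.23) * 50),
        group_fractions = c(0.6, 0.2, 0.2))),
    input = list(),
    signatures = list(fdr_cut = 0.05,
                      covariates = c("sex", "pmi", "rin", "batch",
                                     "pc1", "pc2", "pc3")),
    overlap = list(universe_policy = "intersection", adjust = "matrix"),
    subgroups = list(n_clusters = 3, n_variable_genes = 5000,
                     adjust_covariates = TRUE, covariates = "batch"),
    harmonize = list(covariates = c("age", "pmi", "sex", "rin")),
    deconv = list(n_markers = 100, weighted = TRUE)),
    class = "pipeline_config")
}

load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  cfg <- modifyList(unclass(base), config)
  # Dirichlet group settings are replaced wholesale, never merged per element
  user_mx <- config$sim$mixture_spec
  if (!is.null(user_mx$alpha)) {
    cfg$sim$mixture_spec$alpha <- user_mx$alpha
    if (is.null(user_mx$group_fractions)) {
      cfg$sim$mixture_spec$group_fractions <-
        rep(1 / length(user_mx$alpha), length(user_mx$alpha))
    }
  }
  if (!is.null(user_mx$group_fractions)) {
    cfg$sim$mixture_spec$group_fractions <- user_mx$group_fractions
  }
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    abort(paste0("unknown pipeline config keys: ",
                 paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

p_path <- function(cfg, ...) file.path(cfg$outdir, ...)

write_fragment <- function(cfg, stage, metrics) {
  dir.create(p_path(cfg, "fragments"), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(metrics, p_path(cfg, "fragments",
                                       paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}

read_fragment <- function(cfg, stage) {
  f <- p_path(cfg, "fragments", paste0(stage, ".json"))
  if (!file.exists(f)) {
    abort(sprintf("missing upstream artifact: %s (run stage '%s' first).",
                  f, stage))
  }
  jsonlite::read_json(f, simplifyVector = TRUE)
}

require_file <- function(path, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path))
  }
  path
}

log_msg <- function(cfg, ...) {
  msg <- sprintf(...)
  message("[agingtx] ", msg)
  cat(msg, "\n", file = p_path(cfg, "pipeline.log"), append = TRUE)
}

stage_simulate <- function(cfg) {
  if (!isTRUE(cfg$simulate)) {
    # ingest mode: copy the user-provided paths into the run layout
    need <- c("ref_expr", "ref_meta", "ext_expr", "ext_meta",
              "mix_expr", "mix_meta", "reference")
    for (k in need) {
      require_file(cfg$input[[k]] %||% sprintf("<missing key input.%s>", k),
                   paste0("input ", k))
    }
    for (k in need) file.copy(cfg$input[[k]], p_path(cfg, paste0(k, ".tsv")),
                              overwrite = TRUE)
    return(write_fragment(cfg, "simulate", list(mode = "ingest")))
  }
  sim_args <- cfg$sim %||% list()
  sim_args$seed <- cfg$seed
  sc <- do.call(sim_config, sim_args)

  ref <- simulate_subgroup_cohort(sc)
  ext_sc <- sc
  ext <- simulate_ad_cohort(ext_sc)
  mix <- simulate_mixture_cohort(sc)

  ref$meta$cohort <- "reference"
  ext$meta$cohort <- "external"
  write_expression_tsv(ref$expr, p_path(cfg, "ref_expr.tsv"))
  write_metadata_tsv(ref$meta, p_path(cfg, "ref_meta.tsv"))
  write_expression_tsv(ext$expr, p_path(cfg, "ext_expr.tsv"))
  write_metadata_tsv(ext$meta, p_path(cfg, "ext_meta.tsv"))
  write_expression_tsv(mix$expr, p_path(cfg, "mix_expr.tsv"))
  write_metadata_tsv(mix$meta, p_path(cfg, "mix_meta.tsv"))
  ref_tsv <- data.frame(gene = rownames(mix$reference$values),
                        mix$reference$values, check.names = FALSE)
  utils::write.table(ref_tsv, p_path(cfg, "reference.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    subgroups = ref$truth$subgroups,
    ad_effect = ref$truth$ad_effect,
    age_genes = ref$truth$age_genes,
    shift_genes = ref$truth$shift_genes,
    ext_diagnosis = ext$truth$diagnosis,
    mix_proportions = mix$truth$proportions,
    mix_markers = mix$reference$markers)
  jsonlite::write_json(truth, p_path(cfg, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  write_fragment(cfg, "simulate", list(
    mode = "simulate", n_genes = sc$n_genes,
    n_ref = ncol(ref$expr), n_ext = ncol(ext$expr), n_mix = ncol(mix$expr)))
}

read_truth <- function(cfg) {
  f <- p_path(cfg, "truth.json")
  if (!file.exists(f)) return(NULL)
  jsonlite::read_json(f, simplifyVector = TRUE)
}

stage_signatures <- function(cfg) {
  expr <- read_expression_tsv(require_file(p_path(cfg, "ref_expr.tsv"),
                                           "reference expression"))
  meta <- read_metadata_tsv(p_path(cfg, "ref_meta.tsv"))
  ext_expr <- read_expression_tsv(p_path(cfg, "ext_expr.tsv"))
  ext_meta <- read_metadata_tsv(p_path(cfg, "ext_meta.tsv"))
  sg <- cfg$signatures

  aging_stats <- fit_gene_models(expr, meta, target = "age",
                                 covariates = sg$covariates)
  aging_sig <- derive_signature(aging_stats, fdr_cut = sg$fdr_cut,
                                id = "AGING_REF")
  ad_stats <- fit_gene_models(ext_expr, ext_meta, target = "diagnosis",
                              covariates = intersect(sg$covariates,
                                                     names(ext_meta)),
                              contrast = c("case", "control"))
  ad_sig <- derive_signature(ad_stats, fdr_cut = sg$fdr_cut, id = "AD_EXT")

  readr::write_tsv(aging_stats, p_path(cfg, "aging_stats.tsv"))
  readr::write_tsv(ad_stats, p_path(cfg, "ad_stats.tsv"))
  write_signatures_gmt(list(aging_sig, ad_sig),
                       p_path(cfg, "signatures.gmt"))
  write_signature_tsv(aging_sig, p_path(cfg, "aging_signature.tsv"))
  write_signature_tsv(ad_sig, p_path(cfg, "ad_signature.tsv"))
  write_fragment(cfg, "signatures", list(
    aging_up = length(aging_sig$up), aging_down = length(aging_sig$down),
    ad_up = length(ad_sig$up), ad_down = length(ad_sig$down),
    fdr_cut = sg$fdr_cut))
}

stage_overlap <- function(cfg) {
  expr <- read_expression_tsv(require_file(p_path(cfg, "ref_expr.tsv"),
                                           "reference expression"))
  meta <- read_metadata_tsv(p_path(cfg, "ref_meta.tsv"))
  labels_df <- readr::read_tsv(require_file(p_path(cfg, "subgroup_labels.tsv"),
                                            "subgroup labels"),
                               show_col_types = FALSE)
  sigs <- read_signatures_gmt(require_file(p_path(cfg, "signatures.gmt"),
                                           "signatures"))
  # GMT does not carry gene-level universes; use the tested-gene tables
  aging_stats <- readr::read_tsv(p_path(cfg, "aging_stats.tsv"),
                                 show_col_types = FALSE)
  sigs <- lapply(sigs, function(s) {
    s$universe <- union(aging_stats$gene, c(s$up, s$down))
    s
  })

  # DEG signature of every discovered subgroup against the baseline
  # (largest) subgroup, with the usual covariate adjustment
  meta$cluster <- paste0("S", labels_df$cluster[match(meta$sample_id,
                                                      labels_df$sample_id)])
  base_cl <- names(sort(table(meta$cluster), decreasing = TRUE))[1]
  covs <- intersect(cfg$signatures$covariates, names(meta))
  degs <- list()
  for (cl in setdiff(sort(unique(meta$cluster)), base_cl)) {
    keep <- meta$cluster %in% c(cl, base_cl)
    sub_expr <- expr[, meta$sample_id[keep], drop = FALSE]
    attr(sub_expr, "scale") <- expr_scale(expr)
    st <- fit_gene_models(sub_expr, meta[keep, ], target = "cluster",
                          covariates = covs, contrast = c(cl, base_cl))
    nm <- paste0(cl, "vs", base_cl)
    degs[[nm]] <- derive_signature(st, fdr_cut = cfg$signatures$fdr_cut,
                                   id = nm)
  }

  om <- build_overlap_matrix(degs, sigs[c("AD_EXT", "AGING_REF")],
                             universe_policy = cfg$overlap$universe_policy,
                             adjust = cfg$overlap$adjust)
  readr::write_tsv(om, p_path(cfg, "overlap_long.tsv"))
  wide <- tidyr::pivot_wider(om[, c("row_id", "col_id", "direction", "k")],
                             names_from = "direction", values_from = "k")
  readr::write_tsv(wide, p_path(cfg, "overlap_counts.tsv"))

  ord <- order_by_ad_similarity(degs, sigs["AD_EXT"],
                                baseline = base_cl,
                                universe_policy = cfg$overlap$universe_policy)
  readr::write_tsv(as_tibble(ord), p_path(cfg, "ad_similarity_order.tsv"))

  ad_cells <- om[om$col_id == "AD_EXT", ]
  conc <- ad_cells$adj_p[ad_cells$direction %in% c("UP/UP", "DN/DN")]
  disc <- ad_cells$adj_p[ad_cells$direction %in% c("UP/DN", "DN/UP")]
  write_fragment(cfg, "overlap", list(
    n_cells = nrow(om), baseline_subgroup = base_cl,
    similarity_order = ord$subgroup,
    min_adj_p_concordant = min(conc), min_adj_p_discordant = min(disc)))
}

stage_subgroups <- function(cfg) {
  expr <- read_expression_tsv(require_file(p_path(cfg, "ref_expr.tsv"),
                                           "reference expression"))
  meta <- read_metadata_tsv(p_path(cfg, "ref_meta.tsv"))
  sg <- cfg$subgroups
  work <- if (isTRUE(sg$adjust_covariates)) {
    residualize_covariates(expr, meta, intersect(sg$covariates, names(meta)))
  } else expr
  k_var <- min(sg$n_variable_genes, nrow(work))
  genes <- select_variable_genes(work, k_var)
  wc <- ward_cluster(work, sg$n_clusters, genes = genes)
  conc <- clustering_concordance(work, k_var, sg$n_clusters)
  readr::write_tsv(tidy.ward_clustering(wc), p_path(cfg, "subgroup_labels.tsv"))
  readr::write_tsv(conc, p_path(cfg, "clustering_concordance.tsv"))

  truth <- read_truth(cfg)
  ari_truth <- NA_real_
  if (!is.null(truth$subgroups)) {
    tl <- setNames(truth$subgroups$subgroup, truth$subgroups$sample_id)
    ari_truth <- adjusted_rand_index(wc$labels, tl[names(wc$labels)])
  }
  write_fragment(cfg, "subgroups", list(
    n_clusters = sg$n_clusters, n_variable_genes = k_var,
    cluster_sizes = as.integer(table(wc$labels)),
    concordance_ari = conc$ari[1], truth_ari = ari_truth))
}

stage_harmonize <- function(cfg) {
  ref_expr <- read_expression_tsv(require_file(p_path(cfg, "ref_expr.tsv"),
                                               "reference expression"))
  ref_meta <- read_metadata_tsv(p_path(cfg, "ref_meta.tsv"))
  ext_expr <- read_expression_tsv(require_file(p_path(cfg, "ext_expr.tsv"),
                                               "external expression"))
  ext_meta <- read_metadata_tsv(p_path(cfg, "ext_meta.tsv"))

  common <- intersect(rownames(ref_expr), rownames(ext_expr))
  merged <- cbind(ref_expr[common, , drop = FALSE],
                  ext_expr[common, , drop = FALSE])
  attr(merged, "scale") <- "log2tpm"
  meta <- bind_rows(ref_meta, ext_meta)
  meta$cohort <- rep(c("reference", "external"),
                     c(ncol(ref_expr), ncol(ext_expr)))

  adj <- batch_adjust(merged, meta, batch = "cohort",
                      covariates = cfg$harmonize$covariates)
  qn <- clamp_quantile_normalize(adj)
  write_expression_tsv(qn, p_path(cfg, "harmonized_expr.tsv"))
  write_metadata_tsv(meta, p_path(cfg, "harmonized_meta.tsv"))

  # clean the external case/control set: cluster at k = 2 and drop samples
  # whose diagnosis conflicts with their cluster's majority
  removed <- character()
  retained <- ext_meta$sample_id
  if ("diagnosis" %in% names(ext_meta)) {
    ext_cols <- ext_meta$sample_id
    genes5k <- select_variable_genes(qn[, ext_cols, drop = FALSE],
                                     min(cfg$subgroups$n_variable_genes,
                                         nrow(qn)))
    wc2 <- ward_cluster(qn[, ext_cols, drop = FALSE], 2, genes = genes5k)
    dx <- setNames(ext_meta$diagnosis, ext_meta$sample_id)
    mm <- remove_mixed_samples(wc2$labels, dx)
    removed <- mm$removed
    retained <- mm$retained
    readr::write_tsv(mm$table, p_path(cfg, "mixed_samples.tsv"))
  }
  write_fragment(cfg, "harmonize", list(
    n_genes = length(common), n_samples = ncol(merged),
    n_external_retained = length(retained),
    n_external_removed = length(removed)))
}

stage_project <- function(cfg) {
  qn <- read_expression_tsv(require_file(p_path(cfg, "harmonized_expr.tsv"),
                                         "harmonized expression"))
  meta <- read_metadata_tsv(p_path(cfg, "harmonized_meta.tsv"))
  labels_df <- readr::read_tsv(require_file(p_path(cfg, "subgroup_labels.tsv"),
                                            "subgroup labels"),
                               show_col_types = FALSE)
  ref_ids <- meta$sample_id[meta$cohort == "reference"]
  ext_ids <- meta$sample_id[meta$cohort == "external"]
  # cohort-level adjustment leaves each cohort's internal batch structure in
  # place; residualize it out before distance-based clustering
  if ("batch" %in% names(meta)) {
    meta$.cohort_batch <- paste(meta$cohort, meta$batch)
    qn <- residualize_covariates(qn, meta, ".cohort_batch")
  }
  mixed_f <- p_path(cfg, "mixed_samples.tsv")
  if (file.exists(mixed_f)) {
    mm <- readr::read_tsv(mixed_f, show_col_types = FALSE)
    ext_ids <- mm$sample_id[!mm$mixed]
  }
  # re-cluster the reference inside the harmonized space, then relabel the
  # new clusters by majority vote of the original subgroup labels
  ref_expr <- qn[, ref_ids, drop = FALSE]
  genes <- select_variable_genes(ref_expr,
                                 min(cfg$subgroups$n_variable_genes,
                                     nrow(ref_expr)))
  wc <- ward_cluster(ref_expr, cfg$subgroups$n_clusters, genes = genes)
  orig <- setNames(labels_df$cluster, labels_df$sample_id)
  relabel <- vapply(split(names(wc$labels), wc$labels), function(ids) {
    names(sort(table(orig[ids]), decreasing = TRUE))[1]
  }, character(1))
  ref_labels <- setNames(paste0("S", relabel[as.character(wc$labels)]),
                         names(wc$labels))

  assign <- assign_external_samples(ref_expr, ref_labels,
                                    qn[, ext_ids, drop = FALSE],
                                    genes = genes)
  if ("diagnosis" %in% names(meta)) {
    assign <- left_join(assign, meta[, c("sample_id", "diagnosis")],
                        by = "sample_id")
  }
  readr::write_tsv(assign, p_path(cfg, "projection.tsv"))
  write_fragment(cfg, "project", list(
    n_projected = nrow(assign),
    assignment_table = as.list(table(assign$assigned))))
}

stage_deconvolve <- function(cfg) {
  mix_expr <- read_expression_tsv(require_file(p_path(cfg, "mix_expr.tsv"),
                                               "mixture expression"))
  mix_meta <- read_metadata_tsv(p_path(cfg, "mix_meta.tsv"))
  ref_df <- utils::read.delim(require_file(p_path(cfg, "reference.tsv"),
                                           "cell reference"),
                              check.names = FALSE)
  R <- as.matrix(ref_df[, -1, drop = FALSE])
  rownames(R) <- ref_df[[1]]
  ref <- cell_reference(R)

  markers <- select_markers(ref, n_per_type = cfg$deconv$n_markers)
  props <- dsa_estimate(mix_expr, markers)
  readr::write_tsv(markers, p_path(cfg, "markers.tsv"))
  readr::write_tsv(props, p_path(cfg, "proportions.tsv"))

  comp <- NULL
  if ("group" %in% names(mix_meta) && length(unique(mix_meta$group)) > 1) {
    comp <- compare_proportions(props, setNames(mix_meta$group,
                                                mix_meta$sample_id))
    readr::write_tsv(comp, p_path(cfg, "proportion_tests.tsv"))
  }
  ve <- variance_explained(mix_expr, props, weighted = cfg$deconv$weighted)

  truth <- read_truth(cfg)
  rmse <- NA_real_
  if (!is.null(truth$mix_proportions)) {
    tp <- as_tibble(truth$mix_proportions)
    types <- attr(props, "cell_types")
    Pt <- as.matrix(tp[match(props$sample_id, tp$sample_id), types])
    Pe <- as.matrix(props[, types])
    rmse <- sqrt(mean((Pe - Pt)^2))
  }
  write_fragment(cfg, "deconvolve", list(
    n_markers_used = nrow(markers),
    variance_explained = ve, proportion_rmse = rmse,
    min_omnibus_p = if (!is.null(comp)) {
      min(comp$p_value[comp$test == "omnibus"])
    } else NA_real_))
}

stage_report <- function(cfg) {
  frags <- setNames(lapply(setdiff(pipeline_stages, "report"),
                           function(s) read_fragment(cfg, s)),
                    setdiff(pipeline_stages, "report"))
  report <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    stages = frags,
    outputs = as.list(setNames(
      file.path(cfg$outdir,
                c("ref_expr.tsv", "ext_expr.tsv", "mix_expr.tsv",
                  "signatures.gmt", "overlap_long.tsv",
                  "subgroup_labels.tsv", "harmonized_expr.tsv",
                  "projection.tsv", "proportions.tsv")),
      c("ref_expr", "ext_expr", "mix_expr", "signatures", "overlap",
        "subgroup_labels", "harmonized_expr", "projection", "proportions"))))
  jsonlite::write_json(report, p_path(cfg, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order (simulate/ingest, signatures,
#' overlap, subgroups, harmonize, project, deconvolve, report) under one
#' config and seed; any stage failure aborts with a stage-named error. The
#' run is deterministic given the seed: re-running with the same config
#' produces identical artifacts.
#'
#' @param config Path to a YAML config, or a config list; missing keys take
#'   the values of [default_pipeline_config()].
#' @param outdir,seed Optional overrides of the config's output directory
#'   and seed.
#' @return The report (class `pipeline_report`), invisibly; also written to
#'   `<outdir>/report.json`.
#' @export
run_full <- function(config = list(), outdir = NULL, seed = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- NULL
  for (stage in pipeline_stages) {
    log_msg(cfg, "stage %s (seed %d)", stage, cfg$seed)
    res <- tryCatch(run_stage_impl(stage, cfg), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
    if (stage == "report") report <- res
  }
  invisible(structure(report, class = "pipeline_report"))
}

run_stage_impl <- function(stage, cfg) {
  switch(stage,
    simulate = stage_simulate(cfg),
    signatures = stage_signatures(cfg),
    overlap = stage_overlap(cfg),
    subgroups = stage_subgroups(cfg),
    harmonize = stage_harmonize(cfg),
    project = stage_project(cfg),
    deconvolve = stage_deconvolve(cfg),
    report = stage_report(cfg),
    abort(sprintf("unknown stage '%s'; valid stages: %s", stage,
                  paste(pipeline_stages, collapse = ", "))))
}

#' Run a single pipeline stage
#'
#' Re-runs one stage against the artifacts already present in the config's
#' output directory; upstream artifacts must exist.
#'
#' @param stage_name One of `simulate`, `signatures`, `overlap`,
#'   `subgroups`, `harmonize`, `project`, `deconvolve`, `report`.
#' @inheritParams run_full
#' @return The stage's metrics fragment (list), invisibly.
#' @export
run_stage <- function(stage_name, config = list(), outdir = NULL,
                      seed = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!stage_name %in% pipeline_stages) {
    abort(sprintf("unknown stage '%s'; valid stages: %s", stage_name,
                  paste(pipeline_stages, collapse = ", ")))
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  invisible(run_stage_impl(stage_name, cfg))
}
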