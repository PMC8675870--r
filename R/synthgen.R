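# Synthetic-cohort generator. Emulates the statistical structure the
# downstream stages assume: age-linear effects on planted gene subsets with
# covariate confounding, subgroup shift vectors partially shared with an AD
# case/control effect vector, batch location/scale effects, and bulk mixtures
# of five brain cell types with group-dependent Dirichlet proportions.
# Everything is driven by one integer seed through named substreams so each
# operation is reproducible on its own.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-cohort generator with validated
#' defaults. Defaults emulate a GTEx-hippocampus-like cohort: 56 donors aged
#' 45-70, modest covariate confounding, three aging subgroups with sample
#' fractions (0.6, 0.2, 0.2) whose shift vectors share a configurable
#' fraction of genes (with matching sign) with an AD case/control effect
#' vector, and bulk mixtures of five cell types (neuron, astrocyte,
#' endothelial, microglia, oligodendrocyte) with a neuron-dominant Dirichlet.
#'
#' @param n_genes,n_samples Dimensions of the simulated expression matrix.
#' @param age_range Length-2 numeric, donor age range in years (non-zero
#'   width).
#' @param n_age_genes Number of planted age-associated genes.
#' @param age_slope_sd SD (log2 units per year) of the planted slopes, drawn
#'   from `N(0, age_slope_sd)`.
#' @param covariate_spec Named list: `sex_prob` (P(female)), `pmi_mean`,
#'   `pmi_sd` (hours), `rin_mean`, `rin_sd`, `n_batches`, `batch_sd`
#'   (per-gene batch location offsets), `batch_scale_sd` (log-scale batch
#'   scale effects; 0 disables), `sex_effect_sd`, `pmi_effect_sd`,
#'   `rin_effect_sd`, `pc_effect_sd` (per-gene covariate coefficients).
#' @param subgroup_spec Named list: `n_subgroups`, `fractions` (sum to 1;
#'   first subgroup is the unshifted baseline), `shift_magnitude` (log2
#'   units), `n_shift_genes` per subgroup, `shared_frac` (per subgroup, the
#'   fraction of its shift genes drawn from the AD effect vector with
#'   matching sign; entry 1 is ignored for the baseline).
#' @param ad_spec Named list: `n_cases`, `n_controls`, `effect_magnitude`
#'   (log2 units), `n_effect_genes`, `age_range` for the AD cohort.
#' @param mixture_spec Named list: `n_cell_types`, `markers_per_type`,
#'   `alpha` (list of Dirichlet concentration vectors, one per sample group),
#'   `group_fractions`, `epsilon` (off-type marker leakage, default 0.01),
#'   `ref_level_range` (linear-scale marker expression range), `noise_frac`
#'   (multiplicative Gaussian noise as a fraction of signal).
#' @param noise_sd Residual SD on the log2 scale.
#' @param seed Integer master seed; each operation derives a named substream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples = 60,
                       age_range = c(45, 70),
                       n_age_genes = 100,
                       age_slope_sd = 0.04,
                       covariate_spec = list(),
                       subgroup_spec = list(),
                       ad_spec = list(),
                       mixture_spec = list(),
                       noise_sd = 0.5,
                       seed = 1L) {
  covariate_spec <- modifyList(list(
    sex_prob = 0.3, pmi_mean = 12, pmi_sd = 4, rin_mean = 7.5, rin_sd = 0.5,
    n_batches = 2L, batch_sd = 0.2, batch_scale_sd = 0,
    sex_effect_sd = 0.1, pmi_effect_sd = 0.01, rin_effect_sd = 0.05,
    pc_effect_sd = 0.1), covariate_spec)
  subgroup_spec <- modifyList(list(
    n_subgroups = 3L, fractions = c(0.6, 0.2, 0.2),
    shift_magnitude = 0.8, n_shift_genes = 400L,
    shared_frac = c(0, 0.8, 0.4)), subgroup_spec)
  ad_spec <- modifyList(list(
    n_cases = 59L, n_controls = 19L, effect_magnitude = 1.6,
    n_effect_genes = 600L, age_range = c(71, 95)), ad_spec)
  mixture_spec <- modifyList(list(
    n_cell_types = 5L, markers_per_type = 100L,
    alpha = NULL, group_fractions = 1,
    epsilon = 0.01, ref_level_range = c(5, 15), noise_frac = 0.05),
    mixture_spec)
  if (is.null(mixture_spec$alpha)) {
    # neuron-dominant mean proportions (0.4, 0.2, 0.1, 0.1, 0.2) x alpha0 = 50
    base <- c(0.4, 0.2, 0.1, 0.1, 0.2)
    k <- mixture_spec$n_cell_types
    w <- if (k == 5) base else rep(1 / k, k)
    mixture_spec$alpha <- list(w * 50)
  }
  if (!is.list(mixture_spec$alpha)) mixture_spec$alpha <- list(mixture_spec$alpha)

  cfg <- structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    age_range = as.numeric(age_range), n_age_genes = as.integer(n_age_genes),
    age_slope_sd = age_slope_sd, covariate_spec = covariate_spec,
    subgroup_spec = subgroup_spec, ad_spec = ad_spec,
    mixture_spec = mixture_spec, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes <= 0 || cfg$n_samples <= 0) abort("counts must be positive.")
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) == 0) {
    abort("age_range must have non-zero width.")
  }
  if (cfg$n_age_genes > cfg$n_genes) abort("n_age_genes exceeds n_genes.")
  if (cfg$n_age_genes < 0 || cfg$noise_sd < 0) abort("counts must be positive.")
  sg <- cfg$subgroup_spec
  if (abs(sum(sg$fractions) - 1) > 1e-8) {
    abort("subgroup fractions must sum to 1.")
  }
  if (length(sg$fractions) != sg$n_subgroups ||
      length(sg$shared_frac) != sg$n_subgroups) {
    abort("fractions and shared_frac must have one entry per subgroup.")
  }
  if (any(sg$shared_frac < 0 | sg$shared_frac > 1)) {
    abort("shared_frac entries must lie in [0, 1].")
  }
  for (a in cfg$mixture_spec$alpha) {
    if (any(a <= 0)) abort("Dirichlet concentrations must be positive.")
    if (length(a) != cfg$mixture_spec$n_cell_types) {
      abort("each alpha vector needs one entry per cell type.")
    }
  }
  gf <- rep_len(cfg$mixture_spec$group_fractions,
                length(cfg$mixture_spec$alpha))
  if (abs(sum(gf) - 1) > 1e-8) {
    abort("mixture group fractions must sum to 1 across the alpha groups.")
  }
  invisible(cfg)
}

# Derive a 31-bit substream seed from the master seed and an operation name,
# and evaluate `code` under it, restoring the caller's RNG state afterwards.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_len(nchar(name)) %% 97 + 1))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

# Largest-remainder apportionment of n samples to fractions; deterministic
# and sums exactly to n.
apportion_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))
sample_ids <- function(n, prefix = "s") sprintf("%s%04d", prefix, seq_len(n))

# Shared core: baseline + age effects + covariates + batch + noise.
# Returns list(expr, meta, truth_parts) on the log2 scale.
simulate_core <- function(cfg, sample_prefix = "s", age_range = cfg$age_range,
                          plant_age = TRUE) {
  cs <- cfg$covariate_spec
  genes <- gene_ids(cfg$n_genes)
  samples <- sample_ids(cfg$n_samples, sample_prefix)

  baseline <- rnorm(cfg$n_genes, mean = 6, sd = 1.5)
  age <- runif(cfg$n_samples, age_range[1], age_range[2])
  sex <- rbinom(cfg$n_samples, 1, cs$sex_prob)           # 1 = female
  pmi <- pmax(1, rnorm(cfg$n_samples, cs$pmi_mean, cs$pmi_sd))
  rin <- pmin(10, pmax(2, rnorm(cfg$n_samples, cs$rin_mean, cs$rin_sd)))
  batch <- sample(rep_len(seq_len(cs$n_batches), cfg$n_samples))
  pcs <- matrix(rnorm(cfg$n_samples * 3, 0, 0.02), ncol = 3,
                dimnames = list(NULL, paste0("pc", 1:3)))

  E <- matrix(baseline, nrow = cfg$n_genes, ncol = cfg$n_samples,
              dimnames = list(genes, samples))

  age_truth <- tibble(gene = character(), slope = numeric())
  if (plant_age && cfg$n_age_genes > 0) {
    age_genes <- sort(sample(genes, cfg$n_age_genes))
    slopes <- rnorm(cfg$n_age_genes, 0, cfg$age_slope_sd)
    age_c <- age - mean(cfg$age_range)   # slopes act on centred age
    E[age_genes, ] <- E[age_genes, ] + outer(slopes, age_c)
    age_truth <- tibble(gene = age_genes, slope = slopes)
  }

  # per-gene covariate coefficients (confounding the age model adjusts away)
  cov_effects <- list(
    sex = rnorm(cfg$n_genes, 0, cs$sex_effect_sd),
    pmi = rnorm(cfg$n_genes, 0, cs$pmi_effect_sd),
    rin = rnorm(cfg$n_genes, 0, cs$rin_effect_sd))
  E <- E + outer(cov_effects$sex, sex - mean(sex)) +
    outer(cov_effects$pmi, pmi - mean(pmi)) +
    outer(cov_effects$rin, rin - mean(rin))
  for (j in 1:3) {
    E <- E + outer(rnorm(cfg$n_genes, 0, cs$pc_effect_sd), pcs[, j])
  }

  batch_offsets <- matrix(rnorm(cfg$n_genes * cs$n_batches, 0, cs$batch_sd),
                          ncol = cs$n_batches)
  batch_scales <- matrix(exp(rnorm(cfg$n_genes * cs$n_batches, 0,
                                   cs$batch_scale_sd)),
                         ncol = cs$n_batches)

  noise <- matrix(rnorm(cfg$n_genes * cfg$n_samples, 0, cfg$noise_sd),
                  nrow = cfg$n_genes)
  centred <- noise
  for (b in seq_len(cs$n_batches)) {
    idx <- which(batch == b)
    if (length(idx)) {
      E[, idx] <- E[, idx] + batch_offsets[, b] + centred[, idx] * batch_scales[, b]
    }
  }

  meta <- tibble(
    sample_id = samples, age = age, sex = ifelse(sex == 1, "F", "M"),
    pmi = pmi, rin = rin, batch = paste0("b", batch),
    pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3])

  truth <- list(
    age_genes = age_truth,
    batch = tibble(sample_id = samples, batch = paste0("b", batch)),
    batch_offsets = batch_offsets)
  list(expr = expr_matrix(E, "log2tpm"), meta = meta, truth = truth)
}

# Draw the AD effect vector (gene ids + directions) from the gene pool.
# Uses its own named substream so the subgroup cohort and the AD cohort
# plant the same effect vector under the same master seed.
draw_ad_effect <- function(cfg, genes) {
  if (cfg$ad_spec$n_effect_genes > length(genes)) {
    abort("ad n_effect_genes exceeds n_genes.")
  }
  with_substream(cfg$seed, "ad_effect", {
    ids <- sort(sample(genes, cfg$ad_spec$n_effect_genes))
    tibble(gene = ids,
           direction = sample(c("UP", "DN"), length(ids), replace = TRUE))
  })
}

#' Simulate an aging cohort
#'
#' Log2-scale expression with planted age-linear effects on a random gene
#' subset, covariate confounding (sex, PMI, RIN, genotype PCs), batch
#' location offsets and Gaussian noise. Slopes act on age centred at the
#' middle of `age_range`, so the baseline is the cohort-mean level.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (genes x samples matrix, scale `log2tpm`),
#'   `meta` (tibble of per-sample covariates) and `truth` (planted ground
#'   truth: age genes with slopes, batch assignment and offsets).
#' @export
simulate_aging_cohort <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "aging", {
    core <- simulate_core(config)
    core$truth$age_genes <- core$truth$age_genes
    core
  })
}

#' Simulate an aging cohort with planted subgroups
#'
#' On top of [simulate_aging_cohort()] structure, samples are apportioned to
#' subgroups (largest-remainder rounding of the configured fractions; the
#' first subgroup is the unshifted baseline) and each non-baseline subgroup
#' receives an additive shift vector. A configurable fraction of each shift
#' vector's genes is drawn from the AD effect gene set with matching sign, so
#' subgroup-vs-baseline DEGs overlap the AD signature by construction.
#'
#' @param config A [sim_config()] with at least 2 subgroups.
#' @return List with `expr`, `meta` (gains a `subgroup` column) and `truth`
#'   (adds per-subgroup shift gene tibbles and the AD effect gene set).
#' @export
simulate_subgroup_cohort <- function(config) {
  validate_sim_config(config)
  sg <- config$subgroup_spec
  if (sg$n_subgroups < 2) abort("need at least 2 subgroups.")
  if (sg$n_shift_genes > config$n_genes) {
    abort("n_shift_genes exceeds n_genes.")
  }
  if (any(round(sg$shared_frac * sg$n_shift_genes) >
            config$ad_spec$n_effect_genes)) {
    abort("shared shift genes exceed the AD effect set size.")
  }
  with_substream(config$seed, "subgroup", {
    core <- simulate_core(config)
    genes <- rownames(core$expr)
    counts <- apportion_counts(config$n_samples, sg$fractions)
    labels <- rep(LETTERS[seq_len(sg$n_subgroups)], counts)
    labels <- sample(labels)   # random assignment of samples to subgroups

    ad_effect <- draw_ad_effect(config, genes)
    ad_signed <- setNames(ifelse(ad_effect$direction == "UP", 1, -1),
                          ad_effect$gene)

    shifts <- list()
    for (k in seq_len(sg$n_subgroups)[-1]) {
      lab <- LETTERS[k]
      n_shift <- sg$n_shift_genes
      n_shared <- round(sg$shared_frac[k] * n_shift)
      shared <- if (n_shared > 0) sort(sample(ad_effect$gene, n_shared)) else character()
      pool <- setdiff(genes, ad_effect$gene)
      private <- if (n_shift - n_shared > 0) {
        sort(sample(pool, n_shift - n_shared))
      } else character()
      dirs <- c(ad_signed[shared],
                setNames(sample(c(1, -1), length(private), replace = TRUE),
                         private))
      shift_genes <- c(shared, private)
      idx <- which(labels == lab)
      core$expr[shift_genes, idx] <- core$expr[shift_genes, idx] +
        dirs[shift_genes] * sg$shift_magnitude
      shifts[[lab]] <- tibble(
        gene = shift_genes,
        direction = unname(ifelse(dirs[shift_genes] > 0, "UP", "DN")),
        shared_with_ad = shift_genes %in% shared)
    }
    core$meta$subgroup <- labels
    core$truth$subgroups <- tibble(sample_id = core$meta$sample_id,
                                   subgroup = labels)
    core$truth$shift_genes <- shifts
    core$truth$ad_effect <- ad_effect
    core
  })
}

#' Simulate an AD case/control cohort
#'
#' Cases receive the AD effect vector (additive log2 shifts with planted
#' directions); controls do not. Diagnosis metadata are generated
#' consistently with case/control status: controls get `CDR = 0`,
#' `Braak <= 3`, `CERAD = "NL"`; cases get `CDR >= 1`, `Braak >= 5`,
#' `CERAD = "definite AD"`.
#'
#' @param config A [sim_config()]; `ad_spec` sets cohort sizes, effect
#'   magnitude and the (older) age range.
#' @return List with `expr`, `meta` (gains `diagnosis`, `cdr`, `braak`,
#'   `cerad`, `apoe`) and `truth` (adds the AD effect gene set).
#' @export
simulate_ad_cohort <- function(config) {
  validate_sim_config(config)
  ad <- config$ad_spec
  n <- ad$n_cases + ad$n_controls
  cfg <- config
  cfg$n_samples <- as.integer(n)
  with_substream(config$seed, "ad", {
    core <- simulate_core(cfg, sample_prefix = "p", age_range = ad$age_range)
    genes <- rownames(core$expr)
    ad_effect <- draw_ad_effect(config, genes)
    status <- sample(rep(c("case", "control"), c(ad$n_cases, ad$n_controls)))
    case_idx <- which(status == "case")
    signed <- ifelse(ad_effect$direction == "UP", 1, -1) * ad$effect_magnitude
    core$expr[ad_effect$gene, case_idx] <-
      core$expr[ad_effect$gene, case_idx] + signed

    n_case <- length(case_idx)
    core$meta$diagnosis <- status
    core$meta$cdr <- ifelse(status == "case",
                            sample(c(1, 2, 3), n, replace = TRUE), 0)
    core$meta$braak <- ifelse(status == "case",
                              sample(5:6, n, replace = TRUE),
                              sample(0:3, n, replace = TRUE))
    core$meta$cerad <- ifelse(status == "case", "definite AD", "NL")
    core$meta$apoe <- sample(c("e3/e3", "e3/e4", "e2/e3"), n,
                             replace = TRUE, prob = c(0.6, 0.3, 0.1))
    core$truth$ad_effect <- ad_effect
    core$truth$diagnosis <- tibble(sample_id = core$meta$sample_id,
                                   diagnosis = status)
    core
  })
}

#' Simulate bulk mixtures of cell types
#'
#' Builds a linear-scale cell-type reference whose marker genes are expressed
#' at level `m` in their own type and `m * epsilon` elsewhere, draws
#' per-sample proportions from group-specific Dirichlet distributions, and
#' forms bulk expression as `reference %*% proportions` with multiplicative
#' Gaussian noise (`noise_frac` of the signal).
#'
#' @param config A [sim_config()]; `mixture_spec` controls everything.
#' @return List with `expr` (linear scale, tag `tpm`), `meta` (sample group),
#'   `truth` (true proportion tibble, rows summing to 1) and `reference`
#'   (a [cell_reference()] with markers flagged).
#' @export
simulate_mixture_cohort <- function(config) {
  validate_sim_config(config)
  mx <- config$mixture_spec
  k <- mx$n_cell_types
  types <- if (k == 5) {
    c("neuron", "astrocyte", "endothelial", "microglia", "oligodendrocyte")
  } else paste0("type", seq_len(k))
  with_substream(config$seed, "mixture", {
    genes <- gene_ids(config$n_genes)
    samples <- sample_ids(config$n_samples, "m")
    n_marker <- k * mx$markers_per_type
    if (n_marker > config$n_genes) {
      abort("not enough genes for the requested markers per type.")
    }
    marker_genes <- sort(sample(genes, n_marker))
    marker_type <- rep(types, each = mx$markers_per_type)

    R <- matrix(runif(config$n_genes * k, 0.5, 2), nrow = config$n_genes,
                dimnames = list(genes, types))
    m_levels <- runif(n_marker, mx$ref_level_range[1], mx$ref_level_range[2])
    R[marker_genes, ] <- m_levels * mx$epsilon
    for (i in seq_len(n_marker)) {
      R[marker_genes[i], marker_type[i]] <- m_levels[i]
    }

    groups <- rep(paste0("grp", seq_along(mx$alpha)),
                  apportion_counts(config$n_samples,
                                   rep_len(mx$group_fractions,
                                           length(mx$alpha))))
    P <- matrix(NA_real_, nrow = config$n_samples, ncol = k,
                dimnames = list(samples, types))
    for (i in seq_len(config$n_samples)) {
      a <- mx$alpha[[match(groups[i], unique(groups))]]
      d <- rgamma(k, shape = a, rate = 1)
      P[i, ] <- d / sum(d)
    }

    E <- R %*% t(P)
    if (mx$noise_frac > 0) {
      E <- E * (1 + matrix(rnorm(length(E), 0, mx$noise_frac), nrow = nrow(E)))
      E[E < 0] <- 0
    }
    colnames(E) <- samples

    ref <- cell_reference(R, markers = tibble(gene = marker_genes,
                                              cell_type = marker_type))
    list(
      expr = expr_matrix(E, "tpm"),
      meta = tibble(sample_id = samples, group = groups),
      truth = list(proportions = as_tibble(P, rownames = "sample_id")),
      reference = ref)
  })
}
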