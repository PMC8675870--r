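test_that("OLS on the 5-sample toy matches the closed form", {
  # ages 50..70, values 1..5: slope = 0.2, perfect fit
  expr <- toy_expr(matrix(1:5, nrow = 1), samples = sprintf("s%03d", 1:5))
  meta <- tibble::tibble(sample_id = sprintf("s%03d", 1:5),
                         age = c(50, 55, 60, 65, 70))
  st <- fit_gene_models(expr, meta, target = "age")
  expect_equal(st$estimate, 0.2, tolerance = 1e-12)
  expect_equal(st$se, 0, tolerance = 1e-9)
})

test_that("noiseless planted slopes are recovered exactly and p is tiny", {
  cfg <- clean_config(n_genes = 60, n_samples = 25, n_age_genes = 5, seed = 21)
  sim <- simulate_aging_cohort(cfg)
  st <- fit_gene_models(sim$expr, sim$meta, target = "age")
  est <- st$estimate[match(sim$truth$age_genes$gene, st$gene)]
  expect_equal(est, sim$truth$age_genes$slope, tolerance = 1e-9)
  big <- abs(sim$truth$age_genes$slope) > 0.01
  expect_true(all(st$p_value[match(sim$truth$age_genes$gene[big],
                                   st$gene)] < 1e-12))
})

test_that("per-gene fits agree with an independent moderated-model engine", {
  skip_if_not_installed("limma")
  sim <- simulate_aging_cohort(sim_config(n_genes = 100, n_samples = 30,
                                          seed = 22))
  covs <- c("sex", "pmi", "rin")
  st <- fit_gene_models(sim$expr, sim$meta, target = "age", covariates = covs)
  X <- model.matrix(~ age + sex + pmi + rin, data = sim$meta)
  fit <- limma::lmFit(sim$expr, X)
  expect_equal(st$estimate, unname(fit$coefficients[, "age"]),
               tolerance = 1e-9)
  expect_equal(st$se, unname(fit$sigma * fit$stdev.unscaled[, "age"]),
               tolerance = 1e-9)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  sim <- simulate_aging_cohort(clean_config(n_genes = 10, n_samples = 12,
                                            n_age_genes = 2, seed = 1))
  meta <- sim$meta
  meta$age_copy <- meta$age
  expect_error(fit_gene_models(sim$expr, meta, target = "age",
                               covariates = "age_copy"),
               "rank deficient.*age_copy")
})

test_that("a null cohort yields almost no discoveries and uniform p-values", {
  cfg <- sim_config(n_genes = 2000, n_samples = 60, n_age_genes = 0, seed = 23)
  sim <- simulate_aging_cohort(cfg)
  st <- fit_gene_models(sim$expr, sim$meta, target = "age",
                        covariates = c("sex", "pmi", "rin", "batch"))
  expect_lte(sum(st$fdr <= 0.05) / nrow(st), 0.01)
  ks <- suppressWarnings(stats::ks.test(st$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("covariate adjustment protects slopes from a correlated batch effect", {
  # batch assignment correlated with age + a strong batch offset
  set.seed(31)
  n <- 60
  meta <- toy_meta(n)
  meta$age <- sort(meta$age)
  meta$batch <- rep(c("b1", "b2"), each = n / 2)  # late batch = older donors
  slope <- 0.05
  offset <- ifelse(meta$batch == "b2", 1.5, 0)
  Y <- matrix(rnorm(50 * n, 0, 0.3), nrow = 50)
  Y <- sweep(Y, 2, slope * meta$age + offset, "+")
  expr <- toy_expr(Y)
  with_b <- fit_gene_models(expr, meta, "age", covariates = "batch")
  without_b <- fit_gene_models(expr, meta, "age")
  expect_lt(abs(mean(with_b$estimate) - slope) / slope, 0.1)
  expect_gt(abs(mean(without_b$estimate) - slope) / slope, 0.5)
})

test_that("signature derivation applies the FDR and effect-size rules", {
  st <- tibble::tibble(
    gene = paste0("g", 1:6),
    estimate = c(1, 0.5, 2, -1, -0.5, -2),
    se = 1, statistic = 1,
    p_value = rep(0.01, 6),
    fdr = c(0.01, 0.04, 0.06, 0.01, 0.5, 0.04))
  attr(st, "universe") <- st$gene
  sig <- derive_signature(st, fdr_cut = 0.05, id = "toy")
  expect_setequal(sig$up, c("g1", "g2"))
  expect_setequal(sig$down, c("g4", "g6"))
  # strict effect cut drops |effect| <= 1 from both sets
  sig2 <- derive_signature(st, fdr_cut = 0.05, effect_cut = 1)
  expect_setequal(sig2$up, character(0))
  expect_setequal(sig2$down, "g6")
  # nothing significant -> empty signature
  st$fdr <- 1
  sig3 <- derive_signature(st, fdr_cut = 0.05)
  expect_length(c(sig3$up, sig3$down), 0)
})

test_that("consensus calling matches a brute-force counting oracle", {
  uni <- paste0("g", 1:20)
  set.seed(41)
  sigs <- lapply(1:7, function(i) {
    genes <- sample(uni, 8)
    gene_signature(paste0("s", i), up = genes[1:4], down = genes[5:8],
                   universe = uni)
  })
  cons <- consensus_signature(sigs, min_lists = 2,
                              require_no_conflict = TRUE)
  # oracle: count per gene over all lists
  up_n <- sapply(uni, function(g) sum(sapply(sigs, function(s) g %in% s$up)))
  dn_n <- sapply(uni, function(g) sum(sapply(sigs, function(s) g %in% s$down)))
  expect_setequal(cons$up, uni[up_n >= 2 & dn_n == 0])
  expect_setequal(cons$down, uni[dn_n >= 2 & up_n == 0])
  # invariant to input ordering
  cons2 <- consensus_signature(rev(sigs), min_lists = 2)
  expect_identical(cons$up, cons2$up)
  expect_identical(cons$down, cons2$down)
  expect_error(consensus_signature(sigs, min_lists = 8), "min_lists")
})

test_that("consensus conflict rule excludes genes seen in both directions", {
  uni <- paste0("g", 1:5)
  mk <- function(id, up, dn) gene_signature(id, up, dn, uni)
  sigs <- c(lapply(1:5, function(i) mk(paste0("u", i), "g1", character(0))),
            list(mk("d", character(0), "g1")))
  strict <- consensus_signature(sigs, min_lists = 5)
  expect_length(strict$up, 0)
  loose <- consensus_signature(sigs, min_lists = 5,
                               require_no_conflict = FALSE)
  expect_equal(loose$up, "g1")
})

test_that("down-sampling counts are seeded and degenerate at full size", {
  sim <- simulate_aging_cohort(sim_config(n_genes = 300, n_samples = 40,
                                          n_age_genes = 30, seed = 51))
  full <- downsample_signature_count(sim$expr, sim$meta, n_sub = 40,
                                     n_reps = 4, seed = 1)
  expect_equal(attr(full, "sd"), 0)
  st <- fit_gene_models(sim$expr, sim$meta, target = "age")
  full_count <- length(derive_signature(st)$up) +
    length(derive_signature(st)$down)
  expect_equal(attr(full, "mean"), full_count)

  d1 <- downsample_signature_count(sim$expr, sim$meta, n_sub = 30,
                                   n_reps = 5, seed = 7)
  d2 <- downsample_signature_count(sim$expr, sim$meta, n_sub = 30,
                                   n_reps = 5, seed = 7)
  expect_identical(d1$n_genes, d2$n_genes)
  expect_gt(attr(d1, "sd"), 0)
  expect_error(downsample_signature_count(sim$expr, sim$meta, n_sub = 100,
                                          n_reps = 2, seed = 1), "n_sub")
})

test_that("down-sampled counts of strong planted effects stay near truth", {
  cfg <- sim_config(n_genes = 1000, n_samples = 60, n_age_genes = 100,
                    age_slope_sd = 0.12, noise_sd = 0.3, seed = 52)
  sim <- simulate_aging_cohort(cfg)
  ds <- downsample_signature_count(sim$expr, sim$meta, n_sub = 48,
                                   n_reps = 10, fdr_cut = 0.05, seed = 3)
  expect_gt(attr(ds, "mean"), 70)
  expect_lt(attr(ds, "mean"), 105)
})
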