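test_that("TMM factors: identity, pure scaling, and normalization", {
  set.seed(91)
  counts <- matrix(rpois(400 * 4, 50), nrow = 400)
  m <- toy_expr(cbind(counts[, 1], counts[, 1], counts[, 1]),
                scale = "counts")
  f <- tmm_factors(m)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-12)

  # sample 2 = 2x sample 1: constant M, factor ratio compensates the doubling
  m2 <- toy_expr(cbind(counts[, 1], counts[, 1] * 2), scale = "counts")
  f2 <- tmm_factors(m2)
  expect_equal(unname(f2[2] / f2[1]), 2, tolerance = 1e-9)

  # geometric mean is always 1
  m3 <- toy_expr(counts, scale = "counts")
  f3 <- tmm_factors(m3)
  expect_equal(exp(mean(log(f3))), 1, tolerance = 1e-12)

  # gene-order invariance and common-constant invariance
  f3b <- tmm_factors(toy_expr(counts[sample(400), ], scale = "counts"))
  expect_equal(unname(f3), unname(f3b), tolerance = 1e-12)
  f3c <- tmm_factors(toy_expr(counts * 7, scale = "counts"))
  expect_equal(unname(f3), unname(f3c), tolerance = 1e-9)

  bad <- toy_expr(cbind(counts[, 1], 0 * counts[, 1]), scale = "counts")
  expect_error(tmm_factors(bad), "all-zero")
})

test_that("TMM factors track the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(92)
  counts <- matrix(rnbinom(1000 * 6, mu = 80, size = 3), nrow = 1000)
  counts[1:50, 1:3] <- counts[1:50, 1:3] * 6   # composition bias
  m <- toy_expr(counts, scale = "counts")
  mine <- tmm_factors(m)
  er <- edgeR::calcNormFactors(counts, method = "TMM")
  # our factors absorb library size; edgeR's multiply it
  full <- er * colSums(counts)
  full <- full / exp(mean(log(full)))
  expect_gt(cor(log(unname(mine)), log(full)), 0.99)
  expect_lt(max(abs(log2(unname(mine) / full))), 0.1)
})

test_that("marker selection finds planted exclusive markers", {
  sim <- simulate_mixture_cohort(sim_config(n_genes = 600, n_samples = 10,
                                            seed = 93,
                                            mixture_spec = list(
                                              markers_per_type = 20)))
  mk <- select_markers(sim$reference, n_per_type = 20)
  truth <- sim$reference$markers
  for (tp in unique(truth$cell_type)) {
    expect_setequal(mk$gene[mk$cell_type == tp],
                    truth$gene[truth$cell_type == tp])
  }
  one <- select_markers(sim$reference, n_per_type = 1)
  expect_equal(nrow(one), 5)
  expect_true(all(one$score > 1))
})

test_that("flat genes are never selected ahead of specific ones", {
  R <- rbind(spec1 = c(10, 1), spec2 = c(8, 1), flat = c(5, 5))
  colnames(R) <- c("t1", "t2")
  ref <- cell_reference(R)
  mk <- suppressWarnings(select_markers(ref, n_per_type = 2))
  expect_false("flat" %in% mk$gene[mk$cell_type == "t1"])
  expect_warning(expect_warning(select_markers(ref, n_per_type = 3),
                                "specificity"), "specificity")
})

test_that("DSA recovers noiseless proportions essentially exactly", {
  cfg <- sim_config(n_genes = 800, n_samples = 30, seed = 94,
                    mixture_spec = list(markers_per_type = 30,
                                        noise_frac = 0, epsilon = 0))
  sim <- simulate_mixture_cohort(cfg)
  mk <- select_markers(sim$reference, 30)
  est <- dsa_estimate(sim$expr, mk)
  types <- attr(est, "cell_types")
  truth <- as.matrix(sim$truth$proportions[
    match(est$sample_id, sim$truth$proportions$sample_id), types])
  expect_lt(max(abs(as.matrix(est[, types]) - truth)), 1e-6)
  # rows sum to one, non-negative
  expect_equal(unname(rowSums(as.matrix(est[, types]))), rep(1, 30),
               tolerance = 1e-9)
  expect_true(all(as.matrix(est[, types]) >= 0))
})

test_that("a pure sample gets proportion 1 for its type", {
  cfg <- sim_config(n_genes = 500, n_samples = 20, seed = 95,
                    mixture_spec = list(markers_per_type = 20,
                                        noise_frac = 0, epsilon = 0))
  sim <- simulate_mixture_cohort(cfg)
  # overwrite sample 1 with the pure neuron column
  sim$expr[, 1] <- sim$reference$values[, "neuron"]
  mk <- select_markers(sim$reference, 20)
  est <- dsa_estimate(sim$expr, mk)
  expect_equal(est$neuron[1], 1, tolerance = 1e-9)
  expect_equal(sum(est[1, setdiff(attr(est, "cell_types"), "neuron")]), 0,
               tolerance = 1e-9)
})

test_that("DSA error stays small under 5% noise and degrades gracefully with leakage", {
  noisy <- function(eps) {
    cfg <- sim_config(n_genes = 1500, n_samples = 50, seed = 96,
                      mixture_spec = list(markers_per_type = 50,
                                          noise_frac = 0.05, epsilon = eps))
    sim <- simulate_mixture_cohort(cfg)
    mk <- select_markers(sim$reference, 50)
    est <- dsa_estimate(sim$expr, mk)
    types <- attr(est, "cell_types")
    truth <- as.matrix(sim$truth$proportions[
      match(est$sample_id, sim$truth$proportions$sample_id), types])
    sqrt(mean((as.matrix(est[, types]) - truth)^2))
  }
  rmse <- vapply(c(0, 0.05, 0.2), noisy, numeric(1))
  expect_lt(mean(abs(as.numeric(rmse[2]))), 0.05)  # MAE bounded by RMSE
  # recovery error grows as marker exclusivity is relaxed
  expect_true(all(diff(rmse) > 0))
})

test_that("degenerate marker systems raise errors", {
  X <- matrix(5, nrow = 4, ncol = 6)
  rownames(X) <- paste0("g", 1:4)
  colnames(X) <- paste0("s", 1:6)
  mk <- tibble::tibble(gene = paste0("g", 1:4),
                       cell_type = rep(c("t1", "t2"), each = 2))
  expect_error(dsa_estimate(expr_matrix(X, "tpm"), mk), "singular")
  expect_error(dsa_estimate(expr_matrix(X, "tpm"),
                            tibble::tibble(gene = "gX", cell_type = "t1")),
               "marker genes")
})

test_that("proportion comparisons: null behaviour, planted shifts, 2-group reduction", {
  set.seed(97)
  make_props <- function(P, groups) {
    types <- colnames(P)
    out <- tibble::tibble(sample_id = sprintf("m%03d", seq_len(nrow(P))))
    for (tp in types) out[[tp]] <- P[, tp]
    out$.resid <- 0
    structure(out, class = c("proportion_estimate", class(out)),
              cell_types = types)
  }
  rdiri <- function(n, a) {
    g <- matrix(rgamma(n * length(a), a), ncol = length(a), byrow = TRUE)
    g / rowSums(g)
  }
  # planted neuron drop in group 2
  P <- rbind(rdiri(25, c(40, 20, 10, 10, 20)), rdiri(25, c(15, 25, 12, 18, 30)))
  colnames(P) <- c("neuron", "astro", "endo", "micro", "oligo")
  props <- make_props(P)
  groups <- rep(c("g1", "g2"), each = 25)
  names(groups) <- props$sample_id
  res <- compare_proportions(props, groups)
  expect_lt(res$p_value[res$cell_type == "neuron" & res$test == "omnibus"],
            0.05)
  # two groups: omnibus chi-square equals the rank-sum normal approximation
  omni <- res[res$test == "omnibus" & res$cell_type == "neuron", ]
  pair <- res[res$test == "pairwise" & res$cell_type == "neuron", ]
  expect_equal(omni$p_value, pair$p_value, tolerance = 1e-9)
  expect_error(compare_proportions(props, setNames(c("a", rep("b", 49)),
                                                   props$sample_id)),
               "at least 2")
})

test_that("variance explained spans the designed signal fraction", {
  set.seed(98)
  cfg <- sim_config(n_genes = 600, n_samples = 60, seed = 99,
                    mixture_spec = list(markers_per_type = 30,
                                        noise_frac = 0))
  sim <- simulate_mixture_cohort(cfg)
  mk <- select_markers(sim$reference, 30)
  est <- dsa_estimate(sim$expr, mk)
  # exact linear mixture, no noise -> essentially all variance explained
  expect_gt(variance_explained(sim$expr, est), 0.99)
  # expression independent of proportions -> near zero
  X <- matrix(rnorm(600 * 60, 6, 1), nrow = 600)
  dimnames(X) <- dimnames(sim$expr)
  expect_lt(variance_explained(expr_matrix(X, "tpm"), est), 0.1)
  # half-and-half design lands near 0.5
  half <- 0.5 * scale(t(scale(t(sim$expr)))) + 0.5 * scale(t(scale(t(X))))
  half <- half * 1  # plain numeric matrix
  dimnames(half) <- dimnames(sim$expr)
  ve <- variance_explained(expr_matrix(half, "tpm"), est, weighted = FALSE)
  expect_gt(ve, 0.3)
  expect_lt(ve, 0.7)
})
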