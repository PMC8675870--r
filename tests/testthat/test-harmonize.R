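test_that("log transform is exact and validated", {
  m <- toy_expr(matrix(c(0, 1, 7, 3), 2), scale = "tpm")
  out <- log_transform(m)
  expect_equal(unname(out[, 1]), c(0, 1))
  expect_equal(out[1, 2], 3)  # log2(7 + 1)
  expect_equal(expr_scale(out), "log2tpm")
  expect_error(log_transform(toy_expr(matrix(-1, 1, 2), scale = "tpm")),
               "non-negative")
})

test_that("single batch passes through unchanged", {
  set.seed(81)
  m <- toy_expr(matrix(rnorm(60), 6))
  meta <- toy_meta(10)
  meta$batch <- "b1"
  out <- batch_adjust(m, meta, covariates = c("age", "sex"))
  expect_equal(unname(out), unname(m), tolerance = 1e-9)
})

test_that("a planted constant batch offset is removed essentially exactly", {
  set.seed(82)
  # noiseless: per-gene levels identical within batch, batch 2 offset by 2
  base <- matrix(rnorm(40, 5, 1), nrow = 40, ncol = 12)
  offset <- 2
  Y <- base
  Y[, 7:12] <- Y[, 7:12] + offset
  m <- toy_expr(Y)
  meta <- tibble::tibble(sample_id = colnames(m),
                         batch = rep(c("b1", "b2"), each = 6))
  out <- batch_adjust(m, meta)
  diff <- rowMeans(out[, 1:6]) - rowMeans(out[, 7:12])
  expect_lt(max(abs(diff)), 1e-6)
  expect_error(batch_adjust(m, tibble::tibble(sample_id = colnames(m),
                                              batch = c(rep("b1", 11), "b2"))),
               "at least 2")
})

test_that("batch adjustment preserves a planted age slope within 10%", {
  cfg <- sim_config(n_genes = 800, n_samples = 60, n_age_genes = 60,
                    age_slope_sd = 0.08, seed = 83,
                    covariate_spec = list(batch_sd = 1.0))
  sim <- simulate_aging_cohort(cfg)
  out <- batch_adjust(sim$expr, sim$meta, covariates = c("age", "pmi",
                                                         "sex", "rin"))
  st <- fit_gene_models(out, sim$meta, target = "age")
  tr <- sim$truth$age_genes
  est <- st$estimate[match(tr$gene, st$gene)]
  agg_bias <- sum(est * tr$slope) / sum(tr$slope^2)
  expect_lt(abs(agg_bias - 1), 0.1)
  # and the batch mean differences are gone
  b <- sim$meta$batch[match(colnames(out), sim$meta$sample_id)]
  gap <- rowMeans(out[, b == "b1"]) - rowMeans(out[, b == "b2"])
  expect_lt(mean(abs(gap)), 0.1)
})

test_that("batch adjustment tracks an established empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  set.seed(84)
  n <- 40
  Y <- matrix(rnorm(200 * n, 6, 1), nrow = 200)
  batch <- rep(c("b1", "b2"), each = n / 2)
  Y[, batch == "b2"] <- Y[, batch == "b2"] +
    rnorm(200, 1, 0.3)  # gene-specific offsets
  m <- toy_expr(Y)
  meta <- tibble::tibble(sample_id = colnames(m), batch = batch)
  mine <- batch_adjust(m, meta)
  ref <- suppressMessages(sva::ComBat(dat = Y, batch = batch))
  # same family of adjustment: residual disagreement well under the noise sd
  expect_lt(mean(abs(mine - ref)), 0.1)
  expect_gt(cor(as.numeric(mine), as.numeric(ref)), 0.99)
})

test_that("quantile normalization matches the hand-computed example", {
  m <- toy_expr(cbind(c(1, 2, 3), c(4, 5, 6)))
  out <- clamp_quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))
  # identical samples unchanged (up to clamping)
  m2 <- toy_expr(cbind(c(-1, 2, 3), c(-1, 2, 3)))
  out2 <- clamp_quantile_normalize(m2)
  expect_equal(unname(out2[, 1]), c(0, 2, 3))
})

test_that("quantile normalization invariants: shared multisets, order invariance, ties", {
  set.seed(85)
  X <- matrix(abs(rnorm(50 * 6)) + 0.1, nrow = 50)
  colnames(X) <- sprintf("s%03d", 1:6)
  rownames(X) <- sprintf("g%03d", 1:50)
  out <- clamp_quantile_normalize(expr_matrix(X, "log2tpm"))
  sorted <- apply(out, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  perm <- sample(6)
  out_perm <- clamp_quantile_normalize(expr_matrix(X[, perm], "log2tpm"))
  expect_equal(out_perm, out[, colnames(out_perm)], ignore_attr = TRUE)
  # midrank tie rule: tied entries share the mean of the reference values
  # over the sorted positions they occupy
  Xt <- X
  Xt[3, ] <- Xt[4, ]
  out_t <- clamp_quantile_normalize(expr_matrix(Xt, "log2tpm"))
  ref <- rowMeans(apply(pmax(Xt, 0), 2, sort))
  for (j in 1:6) {
    v <- pmax(Xt[, j], 0)
    expect_equal(out_t[3, j], out_t[4, j])
    expect_equal(out_t[3, j],
                 mean(ref[rank(v, ties.method = "first")[c(3, 4)]]))
  }
})

test_that("quantile normalization agrees with the standard implementation", {
  skip_if_not_installed("limma")
  set.seed(86)
  X <- matrix(abs(rnorm(80 * 5, 5)), nrow = 80)
  colnames(X) <- sprintf("s%03d", 1:5)
  rownames(X) <- sprintf("g%03d", 1:80)
  mine <- clamp_quantile_normalize(expr_matrix(X, "log2tpm"))
  ref <- limma::normalizeQuantiles(X)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("diagnosis rules select exactly the matching samples", {
  meta <- tibble::tibble(
    sample_id = paste0("p", 1:6),
    age = c(75, 80, 68, 90, 72, 85),
    cdr = c(0, 0, 0, 1, 2, 0.5),
    braak = c(2, 3, 1, 5, 6, 4),
    cerad = c("NL", "NL", "NL", "definite AD", "definite AD", "probable AD"))
  normal_rule <- diagnosis_rule(age = c(">", 70), cdr = c("==", 0),
                                braak = c("<=", 3), cerad = c("==", "NL"))
  expect_equal(filter_by_diagnosis(meta, normal_rule), c("p1", "p2"))
  ad_rule <- diagnosis_rule(age = c(">", 70), cdr = c(">=", 1),
                            braak = c(">=", 5),
                            cerad = c("==", "definite AD"))
  expect_equal(filter_by_diagnosis(meta, ad_rule), c("p4", "p5"))
  expect_equal(filter_by_diagnosis(meta, diagnosis_rule()), meta$sample_id)
  expect_error(filter_by_diagnosis(meta, diagnosis_rule(apoe = c("==", "e4"))),
               "apoe")
})

test_that("mixed-sample removal drops exactly the discordant samples", {
  lab <- setNames(rep(c(1, 2), each = 5), paste0("p", 1:10))
  dx <- setNames(rep(c("NL", "AD"), each = 5), paste0("p", 1:10))
  clean <- remove_mixed_samples(lab, dx)
  expect_length(clean$removed, 0)
  # two discordant samples
  dx2 <- dx
  dx2[c("p2", "p8")] <- c("AD", "NL")
  mm <- remove_mixed_samples(lab, dx2)
  expect_setequal(mm$removed, c("p2", "p8"))
  expect_setequal(mm$retained, setdiff(paste0("p", 1:10), c("p2", "p8")))
  # exact tie demands manual resolution
  lab_tie <- setNames(c(1, 1, 2, 2), paste0("p", 1:4))
  dx_tie <- setNames(c("NL", "AD", "NL", "AD"), paste0("p", 1:4))
  expect_error(remove_mixed_samples(lab_tie, dx_tie), "tie")
})

test_that("planted discordance is removed at about the planted rate", {
  set.seed(87)
  n <- 100
  lab <- setNames(rep(1:2, each = n / 2), paste0("p", 1:n))
  dx <- ifelse(lab == 1, "NL", "AD")
  flip <- sample(n, 10)
  dx[flip] <- ifelse(dx[flip] == "NL", "AD", "NL")
  names(dx) <- names(lab)
  mm <- remove_mixed_samples(lab, dx)
  expect_equal(length(mm$removed) / n, 0.1)
})
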