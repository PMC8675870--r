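# Shared fixtures built in code: tiny expression matrices, toy metadata, and
# small helpers used across test files.

toy_expr <- function(values, genes = NULL, samples = NULL,
                     scale = "log2tpm") {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%03d", seq_len(ncol(m)))
  expr_matrix(m, scale)
}

toy_meta <- function(n, age = NULL, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    age = age %||% runif(n, 45, 70),
    sex = sample(c("M", "F"), n, replace = TRUE),
    pmi = runif(n, 5, 20),
    rin = runif(n, 6, 9),
    batch = sample(c("b1", "b2"), n, replace = TRUE),
    pc1 = rnorm(n, 0, 0.02), pc2 = rnorm(n, 0, 0.02),
    pc3 = rnorm(n, 0, 0.02))
}

# a noiseless config with no covariate or batch effects
clean_config <- function(...) {
  sim_config(noise_sd = 0,
             covariate_spec = list(batch_sd = 0, sex_effect_sd = 0,
                                   pmi_effect_sd = 0, rin_effect_sd = 0,
                                   pc_effect_sd = 0),
             ...)
}

# brute-force two-sided Fisher p for a 2x2 table via dhyper (independent of
# the package's enumeration)
fisher_2x2_oracle <- function(tab) {
  k <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); q <- sum(tab[, 1])
  supp <- max(0, q - n):min(m, q)
  probs <- dhyper(supp, m, n, q)
  sum(probs[probs <= dhyper(k, m, n, q) * (1 + 1e-7)])
}
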