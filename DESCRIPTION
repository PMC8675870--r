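Package: agingtx
Title: Brain-Aging Transcriptome Signatures, Subgroups, and Cell-Type Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for comparing normal brain-aging and
    Alzheimer's-disease transcriptomes. Derives directional age-association
    and disease gene signatures from covariate-adjusted per-gene linear
    models, tests directional overlap between signature collections with
    hypergeometric enrichment, discovers aging subgroups by variable-gene
    Ward clustering and orders them by disease similarity, harmonizes
    cohorts with empirical-Bayes batch adjustment and quantile
    normalization, projects external samples onto reference subgroups one
    at a time, and estimates cell-type proportions from bulk expression by
    marker-based digital sorting. Ships a synthetic-cohort generator with
    full ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR,
    sva,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
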