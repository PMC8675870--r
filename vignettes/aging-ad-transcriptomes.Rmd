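---
title: "Comparing brain-aging and Alzheimer's-disease transcriptomes with agingtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing brain-aging and Alzheimer's-disease transcriptomes with agingtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agingtx)
```

## The scientific problem

A recurring observation in bulk brain transcriptomics is that cognitively
normal older donors do not age homogeneously: hierarchical clustering of
hippocampal expression splits them into subgroups, and some subgroups show
expression changes strikingly similar to those seen in late-onset
Alzheimer's disease (AD). Establishing that similarity rigorously requires
a chain of analyses — covariate-adjusted differential expression,
directional gene-set overlap, clustering, cross-cohort harmonization,
sample projection, and cell-type deconvolution — each with choices that
affect the conclusion. `agingtx` packages that chain with every choice
explicit, and pairs it with a synthetic-cohort generator whose ground
truth lets each stage be validated quantitatively.

## Models and procedures

### Per-gene linear models

For gene $g$ with log2-scale expression $y_{gi}$ in sample $i$,

$$ y_{gi} = \beta_{0g} + \beta_{1g}\,t_i + \gamma_g^\top z_i + \varepsilon_{gi}, $$

where $t_i$ is the target (donor age in years, or a 0/1 case indicator)
and $z_i$ the adjustment covariates (sex, PMI in hours, RIN, batch,
genotype PCs). Fits are ordinary least squares — the design is shared
across genes, so one QR decomposition serves all fits — with a two-sided
t test on $\beta_{1g}$ and BH adjustment across genes. An optional
moderation shrinks residual variances toward their pooled mean with a
configurable prior weight (default 0, i.e. plain OLS); we deliberately do
not reproduce any specific empirical-Bayes machinery, keeping the
computation self-contained and exactly testable. Count-scale input is
transformed to $\log_2(\mathrm{CPM} + 0.5)$ first, since the model assumes
continuous roughly homoskedastic expression.

Signatures threshold the adjusted p at `fdr_cut` (default 0.05), split by
effect sign, and optionally require $|\log_2\mathrm{FC}|$ strictly above
`effect_cut`. Consensus signatures require a gene to appear in the same
direction in at least `min_lists` collections; the shipped configurations
read "more than 4" as $\ge 5$ and "at least 9" as $\ge 9$, and by default
exclude genes that ever appear in the opposite direction
(`require_no_conflict = TRUE`) — "consistently regulated" is taken to mean
no conflicting evidence, a stricter and more defensible reading than
majority vote, which remains available.

### Directional overlap enrichment

For row signature $R$ and column signature $C$ with sets of sizes $n_1,
n_2$ inside a universe of $N$ tested genes, the overlap $k$ in each
direction pair is tested with the one-sided hypergeometric upper tail
$P(X \ge k)$. Three choices are parameters because no single convention
dominates:

* **Universe** (`universe_policy`): default is the *intersection* of the
  two signatures' tested-gene universes — conservative, since genes never
  tested in one cohort cannot contribute overlap; `union` and `fixed` are
  available.
* **Adjustment scope** (`adjust`): default BH across the whole matrix of
  cells; per-row adjustment is available.
* **Ordering score**: the claim "subgroup B is more AD-similar than C" is
  operationalized as
  $s(B) = \sum_{\text{concordant cells}} -\log_{10} p^{adj} -
  \sum_{\text{discordant cells}} -\log_{10} p^{adj}$, summed over AD
  signatures. The score is monotone in exactly the evidence one reads off
  an overlap heatmap (strong same-direction cells push a subgroup up,
  strong cross-direction cells push it down), and the baseline subgroup
  scores 0 by construction. Ties are broken lexicographically and flagged.

### Subgroup discovery and projection

Clustering uses Ward.D2 on Euclidean distances between samples over the
top 5,000 most variable genes (variance ties broken by gene id, so the
selection is deterministic), with the number of clusters a parameter
(default 3) — we provide no automatic $k$ selection, since the reference
analyses chose $k$ by inspection. Samples are ordered by id before
clustering so results cannot depend on column order.

Whether to residualize covariates out of the expression before clustering
was genuinely open. We expose the toggle, but the pipeline default is to
residualize **batch only**. The reason is geometric: with $n \approx 56$
samples, residualizing on low-variance continuous covariates (genotype
PCs especially) gives a few samples high leverage; any chance correlation
between subgroup membership and the covariate then transfers part of the
subgroup shift into the fitted covariate effect and smears its negative
image onto unrelated high-leverage samples. In our simulations this
single choice moved subgroup-recovery ARI from an unstable 0.63–0.94
(full covariate set) to consistently 1.0 (batch only) at identical effect
sizes. Batch is categorical and balanced, so its removal has no such
pathology.

External samples are projected *one at a time*: the sample is appended to
the reference matrix, the combined set re-clustered at the reference
$k$, clusters mapped to reference subgroups by majority vote of their
original members, and the sample inherits its cluster's label. A cluster
with no strict majority yields `"ambiguous"` rather than a silent
arbitrary label.

### Harmonization

Merging two cohorts uses: $\log_2(\mathrm{TPM}+1)$; a parametric
empirical-Bayes location/scale batch adjustment written for this package
(per gene: fit batch indicators plus covariates, standardize by the
batch-size-weighted grand mean and pooled variance, shrink per-batch
means and variances toward across-gene moment-matched priors — normal on
means, inverse-gamma on variances — in a single pass, remove the shrunken
batch effects, re-add the covariate fit); clamping of negatives to 0;
and quantile normalization in which every sample's sorted values are
replaced by the across-sample mean of sorted values, ties receiving the
mean of the reference values over the positions they occupy. Exact
numerical parity with any existing batch-correction package is a
non-goal; the contract — batch location/scale effects removed, covariate
effects preserved — is what the tests pin down, and an independent
established implementation is used as a cross-check at tolerance in the
test suite.

Two consequences of this design are worth stating because they shape
results. First, when diagnosis is confounded with cohort (all cases
external), removing the cohort mean necessarily absorbs the
cohort-average part of the disease effect; only the within-cohort
deviation (a fraction $n_{\text{controls}}/n$ of the effect) survives
into cross-cohort comparisons. Second, cohort-level adjustment leaves
each cohort's *internal* batch structure untouched, so the projection
stage residualizes cohort×batch before any distance-based step.
Quantile normalization by default uses all genes (not the 5,000-gene
clustering subset): normalization is a property of the full sample
distribution.

Diagnosis filters are conjunctions of field/operator/value clauses, e.g.
neuropathologically normal = (age > 70, CDR = 0, Braak ≤ 3, CERAD "NL")
and definite AD = (age > 70, CDR ≥ 1, Braak ≥ 5, CERAD "definite AD").
"Mixed" samples — those whose 2-cluster assignment conflicts with their
cluster's majority diagnosis — are removed before contrast analyses; an
exact within-cluster diagnosis tie is an error demanding manual
resolution rather than a coin flip.

### Deconvolution

TMM scale factors follow the standard trimmed-mean-of-M-values recipe
(reference = sample whose upper quartile is closest to the mean upper
quartile; 30% two-sided trim on M, 5% on A; precision weights; factors
normalized to geometric mean 1). Our factors absorb library size —
dividing a sample by its factor puts it on the common scale — which is
the convention the recovery tests use directly.

Markers are the `n_per_type` (default 100) genes with the highest
specificity score (expression in the type over the maximum across other
types). Digital sorting then uses that marker means are proportional to
cell-type fractions: with $m_{ij}$ the mean marker expression of type $j$
in sample $i$, solve $\min_x \lVert Mx - \mathbf 1\rVert^2$ for positive
$x_j = 1/s_j$ and set $p_{ij} = m_{ij} x_j$, clipping negatives and
renormalizing rows to 1. Log-scale input is de-logged ($2^x - 1$) first,
because mixing is linear in expression space. Variance explained is the
per-gene $R^2$ of expression on the proportion matrix (intercept
included, one column dropped since rows sum to 1), averaged with
gene-variance weights by default — the weighted mean answers "how much of
the total expression variation do proportions explain", the unweighted
option treats genes equally.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults emulate a
GTEx-hippocampus-like design and were chosen once, for recoverability of
the planted structure at realistic magnitudes:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 56 | hippocampal cohort scale |
| `age_range` | 45–70 years | older-adult span with usable slope leverage |
| `n_age_genes`, `age_slope_sd` | 100, 0.04 log2/yr | subtle, partially detectable aging effects |
| `noise_sd` | 0.5 log2 units | typical residual SD of bulk log expression |
| subgroup fractions | (0.6, 0.2, 0.2) | one dominant healthy subgroup, two minor ones (≈ 34/11/11 of 56) |
| shift vectors | 0.8 log2 × 400 genes | crisp but not caricatural cluster separation |
| `shared_frac` | (0, 0.8, 0.4) | plants the AD-similarity order B > C > A |
| AD cohort | 59 cases / 19 controls, 1.6 log2 × 600 genes | definite-AD vs control contrast; strong effects of the kind |log2FC| > 1 filters select |
| cell types | 5 (neuron, astrocyte, endothelial, microglia, oligodendrocyte), 100 markers each, marker leakage ε = 0.01 | marker-exclusivity assumption, violable for robustness tests |
| Dirichlet | neuron-dominant, α₀ = 50 | realistic proportion spread |

The AD effect magnitude deserves a note: because the merged-cohort
correction is diagnosis-confounded, only ~24% of the case effect survives
harmonization, so a planted effect comparable to the subgroup shifts
would make external cases *provably* closer to the healthy centroid even
without noise. 1.6 log2 units keeps the planted AD-similarity
recoverable and is within the range of reported definite-AD contrasts.

One master seed drives a named substream per operation (aging, subgroup,
ad, mixture, ad_effect), so each cohort is reproducible on its own and
the subgroup and AD cohorts share one AD effect vector under one seed.
Subgroup sample counts use largest-remainder rounding (deterministic,
sums exactly to $n$). Noise is additive Gaussian on the log2 scale,
matching the linear-model assumptions downstream.

What the generator does **not** emulate: negative-binomial count noise,
read-level artifacts, isoform structure, correlated gene modules,
nonlinear age trajectories, and cell-composition-driven expression in the
non-mixture cohorts. Passing tests therefore demonstrate that the
algorithms recover the structures they assume, at realistic magnitudes —
not that those assumptions hold in any particular real data set.

## Numerical choices and degenerate inputs

* `fisher_exact_rxc` enumerates all margin-fixed tables (probability ≤
  observed, with a $10^{-7}$ relative tolerance as is conventional) and
  refuses tables whose enumeration bound exceeds `cap` (default 5e7) —
  correctness-first at desk scale, where the 3×2 tables of interest have
  a few hundred candidate tables.
* Rank tests use midranks with tie-corrected variance; the rank-sum test
  enumerates exactly when both samples have ≤ 10 untied observations.
  All-tied inputs return $p = 1$ (no evidence) rather than NaN.
* BH adjustment never decreases a p-value and preserves order, but BH
  outputs are not fixed points of BH in general; only tied/constant
  plateaus are idempotent, and the tests assert exactly that.
* `batch_adjust` guards the noiseless limit: zero pooled variances are
  floored, empty scale factors fall back to 1, and a zero-variance prior
  (identical batch effects across genes) collapses the shrinkage to the
  common mean — so a planted constant offset is removed to numerical
  precision. Batches of size 1 are an error (variance undefined).
* Ward clustering sorts samples by id first; tie-breaking is therefore a
  function of the data, not the call order. The leave-one-in projection
  returns `"ambiguous"` on majority ties.
* DSA raises an error when the marker-mean system is singular
  (`rcond < 1e-12`) or yields non-positive scale factors, rather than
  returning clipped nonsense.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run on: 2,000-gene × 60-sample
aging cohorts (slope recovery, realized FDR), 6,000-gene × 56-sample
subgroup cohorts (top-5,000 clustering, concordance, overlap,
projection), 2,000-gene × 50-sample mixtures (deconvolution), and pooled
projection over 10–20 seeded replicates of the 56+78-sample merged
design. These sizes were chosen as the smallest at which the planted
structures are comfortably identifiable, keeping the whole suite fast on
a single CPU.

## Known limitations

* The similarity ordering is our operationalization of a verbal
  argument; other monotone summaries of the same cells are defensible.
* The overlap test's universe, adjustment scope, and the consensus
  conflict rule are conventions, exposed as parameters rather than
  settled claims.
* Harmonization under diagnosis-confounded batch is intrinsically lossy
  (see above); no parameter choice in this package can recover the
  absorbed cohort-mean component.
* The DSA formulation here is the sum-to-one least-squares variant;
  other published digital-sorting variants differ in their constraint
  handling and will not agree numerically.
* `fisher_exact_rxc` is for desk-scale tables only, by design.
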