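---
title: "Sparse model selection for behavioral screening score sheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse model selection for behavioral screening score sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinician-administered screening instruments for autism spectrum
disorder (ASD), such as the ADOS, consist of 28–30 behavioral items
coded 0–3 (higher = more severe), with special codes 8, 9 or a blank
cell recording that an item could not be assessed. Administering the
full instrument takes about an hour; a classifier that reaches
comparable discrimination from a handful of items would shorten
screening and relieve clinical bottlenecks. The statistical obstacles
are severe class imbalance (well over 90% of score sheets in research
repositories come from ASD cases), heavy per-item missingness (up to
~79% on some items), and strong item–item correlation, which makes any
single model's feature choice unstable.

`sparsescreen` implements a two-phase pipeline that addresses feature
instability by *consensus across classifiers*: many differently-biased
models are each pushed toward sparse solutions, and the features they
agree on form the reduced screening set.

## The model

**Preprocessing.** Each of the $n$ items contributes two columns: the
raw 0–3 code (missing positions filled with 0, the least-severity
neutral point) and a paired binary indicator `item_missing` ∈ {0, 3}
that is on exactly when the code was 8, 9 or blank. Missingness is a
feature, not a nuisance: the inability to assess a behavior can itself
carry diagnostic signal, and for linear classifiers mixing "missing"
into an otherwise ordinal severity column would be incoherent. Age is
min–max rescaled onto [0, 3] and gender coded {0, 3} (male = 0,
female = 3; the instrument scale's two extremes, which end is which is
arbitrary but fixed), giving $2n + 2$ features — 58 for a 28-item
instrument. Labels are ordinal (non-ASD 0, spectrum 1, autism 2) and
binary (ASD = spectrum or autism).

**Phase 1 — penalized selection.** For each classifier configuration
$c$ with hyperparameter grid $\Theta_c$, a stratified 10-fold
cross-validation on the 80% training partition evaluates every grid
point $\theta$ by the L0-penalized objective

$$ M_{\text{sparsity}}(\theta) \;=\; \mathrm{AUC}(\theta)
   \;-\; \mu\,\frac{\#\text{features used}(\theta)}{\#\text{features total}}, $$

with $\mu = 0.1$ by default and AUC the ROC area (precision–recall
variants are available via `auc_kind`). The penalty is an explicit
price per feature: it plays the role of an L0 norm on the feature set,
reaching models (trees, kernel machines) that L1 penalties cannot
sparsify directly. On top of the penalty, the **one-standard-error
rule** selects, among all grid points whose mean objective is within
one standard error of the best point's, the most parsimonious one —
largest penalty, smallest k, shallowest or fewest trees. The SE is the
sample standard deviation of the per-fold objectives divided by
$\sqrt{10}$; parsimony is compared lexicographically with the
sparsifying axis first, and residual ties resolve to the earliest grid
row, so selection is deterministic.

**Consensus.** Each configuration's selected model is refit per fold;
the *feature-usage heatmap* records, per (classifier, feature), the
fraction of folds whose selected model used the feature. Two heatmaps
are built from the same fold-level results: with the L0 penalty and
with the penalty switched off (the one-SE rule applies to both).
Features are ranked by their mean usage across classifiers in the
penalized heatmap; ties at the k-boundary are broken by usage in the
non-penalized heatmap, then by feature name. The top 5 and top 10
features form the reduced-5 and reduced-10 sets.

**Phases 2–3.** The final classifier is retuned on the reduced set by
the same stratified CV but maximizing plain AUC_ROC — the feature set
is already fixed, so no sparsity pressure remains — and then evaluated
once on the held-out 20%, reporting ROC AUC, precision–recall AUC with
either class as positive, and the thresholded panel (precision,
recall/sensitivity, specificity, balanced accuracy, F1; ASD positive).

## The classifier registry

`build_registry()` enumerates 17 configurations in five families.

| family | configurations | sparsifying axis | imbalance |
|---|---|---|---|
| penalized linear regression (ordinal 0/1/2 target) | linear regression, lasso, ridge, elastic net, relaxed lasso | penalty λ | undersample to 1:1 |
| nearest neighbors | nearest shrunken centroids | shrinkage Δ | undersample |
| general linear classifiers | shrinkage LDA, logistic L1, logistic L2 | shrinkage / λ | class weights |
| support vector machines | linear (L1), polynomial, radial, exponential | λ, or wrapper k | class weights |
| tree-based | decision tree, random forest, gradient boosting, AdaBoost | depth / tree count | class weights |

Kernel SVMs have no feature-sparsifying parameter of their own, so they
sit behind a feature-selection wrapper (ANOVA F ranking by default;
lasso-support and tree-importance wrappers are available) whose `k`
becomes the sparsifying axis. Tree-based models use their own
structural axes: depth limits a single tree, tree count limits the
ensembles. Plain linear regression has no sparsifier at all; it keeps a
degenerate single-point grid and, as expected, uses nearly every
feature and votes weakly in the consensus.

Several components are implemented in-package because they are part of
the method rather than a standard library call:

* **L1-penalized linear SVM** — squared-hinge loss with an L1 penalty,
  solved by proximal gradient (FISTA) with backtracking on
  standardized features; deterministic, tolerance 1e-9 on the relative
  objective, at most 1000 iterations.
* **Nearest shrunken centroids** — soft-thresholded class centroids
  with the usual pooled within-class standard deviations plus a median
  offset; the score is the difference of class discriminants.
* **Shrinkage LDA** — pooled weighted covariance shrunk convexly
  toward its scaled identity, $\Sigma_s = (1-s)\Sigma + s\,
  (\mathrm{tr}\,\Sigma/p)\,I$; the shrinkage weight $s$ is the
  parsimony axis. (Instrument tables describing this model are
  ambiguous between L1-penalized and shrinkage LDA; the shrinkage
  reading matches the printed "S = 0.8"-style optima.)
* **AdaBoost** — SAMME over depth-1 `rpart` stumps, initial
  observation weights at the inverse class frequencies.
* The **exponential-kernel SVM** is the Laplacian kernel
  $\exp(-\gamma\lVert x - x'\rVert_1)$, the standard reading of
  "exponential" as distinct from the Gaussian radial kernel.

Standard steps ride on standard packages: glmnet for every lasso /
ridge / elastic-net / logistic path, e1071 and kernlab for the kernel
machines, rpart / ranger / xgboost for the trees.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mu` | 0.1 | price of using all features, in AUC units; 0.1 trades ~1 AUC point for a large reduction in feature count |
| `n_folds` | 10 | selection and tuning CV folds, stratified on the binary label |
| `test_fraction` | 0.2 | held-out fraction, stratified |
| penalty grids | $10^{-3}..10^{3}$ | log-spaced; selected optima sit well inside |
| wrapper `k` | 2–40 | feature-count ladder, pruned to the feature total |
| tree depth / count | 1–6 / 10–200 | parsimony axes for the tree family |
| `threshold` | 0.5 or 0 | decision cutoff: 0.5 for probability scorers, 0 for margins; a free parameter of `evaluate_on_test()`, never baked into the AUCs |

## The synthetic generator

Real score-sheet repositories are access-restricted, so the package
ships a generator whose defaults *are* the study conditions used by the
tests: 28 items, three diagnostic classes at proportions
(0.05, 0.25, 0.70) — i.e. 95% ASD, matching the extreme imbalance of
research repositories — ages and male:female ratios per class patterned
on a verbally-fluent-module cohort (controls ≈ 109 ± 35 months, ~50%
male; cases ≈ 115 ± 38 months, ~84% male), and item codes from a
latent Gaussian: a shared per-subject factor with loading
`item_correlation` (default 0.3) plus idiosyncratic noise, shifted by
`effect_size × class` for the planted informative items and cut at
fixed thresholds (0.25, 1.0, 1.75) into codes 0–3. Class counts are
apportioned exactly by largest-remainder rounding, so stratification is
testable as an identity rather than in expectation. Missing answers
are drawn per item and coded 8, 9 or blank with equal probability —
the pipeline must treat all three identically, and the generator makes
that a testable contract. Missingness can optionally rise with class
severity (`missing_informative_*`), planting signal in an indicator
column.

For the planted-recovery property the tests use `effect_size = 1.2`
("strong effect": roughly one and a quarter latent standard deviations
per class step, which puts single-item AUCs around 0.8 — informative
but far from trivially separable) at n = 2000 with 5 informative items
among 28 and seven sparse linear configurations, five seeds. These
sizes were chosen as the smallest at which the consensus behaves like
an ensemble rather than a coin flip.

What the generator does **not** emulate: real item semantics and their
clinically structured correlations (a single latent factor is a crude
stand-in), informative-missingness mechanisms tied to verbal ability,
repository-specific administration effects, and label noise in
best-estimate diagnoses. Passing tests therefore demonstrate that the
machinery recovers structure it is pointed at under realistic
imbalance, missingness and correlation — not that the recovered
features would coincide with any clinical instrument's.

## Numerical choices

* A coefficient counts as nonzero when its magnitude on standardized
  features exceeds 1e-8; this guards feature counting against
  floating-point residue.
* glmnet models are fit on a fixed log-spaced lambda path containing
  the requested value, as glmnet recommends, and coefficients are read
  at the exact grid value. On (near-)separable folds the smallest path
  lambdas may hit glmnet's iteration cap while the objective is
  already flat; that routine path warning is muffled.
* Undersampling draws happen inside training folds only — validation
  folds keep the natural imbalance so fold AUCs are unbiased — and are
  seeded per fold, so results are bit-reproducible.
* Fold assignment depends only on the labels and the seed; all
  configurations in one run share the same resampling frame, which the
  cross-classifier heatmap presumes.
* Kernel-SVM decision scores are oriented so that higher = more
  ASD-like by comparing class-conditional mean decision values on the
  training data (library sign conventions differ).
* Degenerate cases are explicit: a wrapper that selects nothing yields
  a constant scorer with zero features; zero-range age columns are
  zeroed with a warning; zero-denominator confusion metrics are `NA`
  with a warning, never silently 0; constant columns get `NA`
  correlations.

## Design decisions

* **Fill value 0** at missing positions of a base column: the paired
  indicator carries the missingness information, and 0 is the neutral
  least-severity point of the scale. Any constant fill is equivalent
  for tree splits; for linear models 0 avoids injecting severity.
* **Raw codes kept**: original codes of 3 are *not* collapsed to 2 —
  that conversion belongs to the instrument's own scoring algorithm,
  which is out of scope here.
* **Age scaling is computed on the training partition only** and
  applied (clamped) to the test partition, so no test information
  leaks into preprocessing.
* **Half-up rounding** for per-class test counts, making the split
  sizes exact and testable.
* **Relaxed lasso** is the canonical two-stage form: lasso support,
  then unpenalized refit on the support (lightly ridged only if
  singular).
* **Aggregate usage is the unweighted mean** of classifier-level fold
  fractions: the configurations vote as equals. Degenerate voters
  (mean AUC ≤ 0.55) can be excluded with `exclude_degenerate = TRUE`,
  but are kept by default since exclusion is a judgment call, not part
  of the selection rule.
* **Phase 2 drops the wrapper axis** entirely: retuning maximizes AUC
  over the remaining hyperparameters with the reduced features fixed.
* The reduced-10 composition rule is *primary ranking + secondary
  tie-break* throughout. Published analyses of this kind sometimes
  blend members from both heatmaps by inspection; the package
  implements the only fully algorithmic reading, and `tie_log` makes
  every secondary-heatmap invocation auditable.
* The objective's AUC flavor defaults to ROC; PR variants are
  configurable because either is defensible under heavy imbalance.
* The SE in the one-SE rule is taken over fold objectives — the
  natural estimator given the CV frame; no alternative resampling
  scheme is implied.

## Problem sizes used by the shipped checks

The test suite exercises the full registry on a 60-subject cohort,
oracle comparisons on 30-point metric instances (100 draws) and 200
randomized one-SE grids, and the planted-recovery study at n = 2000 ×
5 seeds with the seven glmnet-backed/linear configurations; the
acceptance script runs one full pipeline at n = 2000 plus a small
determinism replay at n = 400. These sizes keep a complete run on a
single CPU in minutes while leaving the stochastic margins wide.

## Known limitations

* The exponential-kernel SVM is retained for registry completeness but
  — as in the analyses this pipeline descends from — tends to perform
  at chance under heavy imbalance with the default bandwidth.
* Ridge, plain linear regression and shrinkage LDA cannot reach truly
  sparse solutions (their coefficients are dense); the L0 penalty can
  only prefer other grid points, so these rows vote broadly on the
  heatmap. That is faithful to the method, not a defect, but it means
  the consensus depends on having genuinely sparsifiable families in
  the mix.
* `screen_pipeline()` runs configurations sequentially; determinism is
  guaranteed only in this single-process mode.
* Synthetic cohorts cannot validate clinical feature identity — only
  the selection machinery. Conclusions about real instruments require
  the restricted repositories.
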