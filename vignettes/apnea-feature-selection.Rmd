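---
title: "Wrapper feature selection for sleep-apnea screening tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper feature selection for sleep-apnea screening tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneafs)
```

## Scope and model

`apneafs` classifies obstructive sleep apnea from a mixed-type clinical
table: 31 features (20 numeric, 11 nominal) and a binary outcome, with the
class of interest ("witnessed apnea") coded 1. The pipeline is
preprocessing, demographic grouping, classification, BPSO wrapper feature
selection, and multi-metric evaluation. This vignette records the model
assumptions, the tunable parameters, and the design decisions taken where
the procedure was genuinely underdetermined.

### Preprocessing

* **Sparsity rule.** Columns, then rows, whose missing fraction *strictly
  exceeds* 0.5 are removed (`drop_sparse()`); a column at exactly 50% is
  kept. Column-first order is a package choice — the rule itself does not
  fix it — and matters only when a sparse row overlaps a sparse column.
* **Imputation.** Column mean (numeric) or mode (nominal; ties resolve to
  the earlier level, making the operation deterministic). Mean imputation
  leaves the column mean unchanged, which the tests assert as a fixed-point
  property.
* **Normalization.** Min–max to [0,1] per numeric column. A degenerate
  column (`max == min`) maps to 0: the formula is undefined there and 0
  preserves the range contract. Parameters are returned so the identical
  affine map can be replayed on new rows; replaying them on the fitting
  table reproduces it exactly.
* **Leakage stance.** Imputation and normalization are fit on the full
  table before cross-validation, reproducing the reference protocol in
  which preprocessing precedes classification. This slightly optimistic
  convention is deliberate and documented; fold-wise standardization is
  available inside `knn_spec(standardize = TRUE)`, which z-scores with
  training-fold statistics only.

### Grouping

`split_groups()` partitions by race, sex, or age. The age rule is
`age <= 50` versus `age > 50` (threshold inclusive below, configurable in
years); grouping therefore happens **before** normalization in
`run_experiment()`, since a min–max-scaled age no longer lives on the year
scale. Race and sex groups drop their now-constant grouping column (a
31-feature table yields 30-feature groups); age groups keep the age column,
matching the feature counts of the motivating study's grouped tables.

### Classification

The first-class classifiers are weighted kNN and a random-subspace linear
discriminant ensemble (30 learners, subspace dimension 16, averaged
posteriors), the two that carry the headline comparisons. kNN supports
euclidean, cityblock, cosine, correlation (1 − Pearson), spearman
(1 − Spearman across features) and hamming distances; equal, inverse (1/d)
and squared-inverse (1/d²) vote weights, with exact matches dominating any
weighted vote; tied votes fall back to the training majority class.
Cross-validation is stratified 10-fold by default and pools out-of-fold
predictions into a single confusion matrix (micro aggregation): the printed
accuracies of the reference tables are consistent with whole-sample counts,
not per-fold averages.

Two metric conventions deserve emphasis:

* The comparison tables' "AUC" column satisfies `(TPR + TNR) / 2` exactly —
  it is balanced accuracy, not a ROC integral. `confusion_metrics()`
  implements that convention and a genuine rank-based ROC AUC is exposed
  separately as `roc_auc()`.
* The positive class is configurable (`positive_label`); the default treats
  label 1 (apnea) as positive. The published grouped tables are internally
  consistent with the opposite convention in at least one group, so both are
  supported rather than guessing silently.

`mean_rank()` ranks classifiers within each metric column (descending,
average ranks on ties) and averages across columns. Reproducing the printed
nine-classifier table recovers eight of the nine published mean ranks
exactly; the printed value for the decision tree (8.97) computes to 8.79
from its own columns and is asserted at the recomputed value in the tests —
an apparent digit transposition in the source.

### Binary PSO

Velocity update per dimension:
`v' = ω v + c1 r1 (pbest − x) + c2 r2 (gbest − x)`, clamped to ±6, with
fresh uniform `r1, r2` per dimension. Bits are then redrawn through an
S-shaped transfer function `S(v)`; the four family members divide the
velocity by 1/2, 1, 2, 3 inside the logistic, giving origin slopes 1/2,
1/4, 1/8, 1/12.

* **Polarity.** The published position rule as printed assigns the bit 0
  when `rand < S(v)`, which inverts the convention of the binary-PSO
  transfer-function literature it builds on and would make large positive
  velocities suppress selection. The default is the standard convention
  (bit 1 with probability `S(v)`); the printed rule is available via
  `polarity = "as_printed"`, and the two produce complementary bits on a
  shared random stream.
* **Continuous position update.** In binary mode the additive position
  update is unused; the bit redraw alone defines the position. This is the
  standard BPSO reading.
* **Unstated constants.** Swarm size 10, 100 iterations, ω decayed linearly
  0.9 → 0.4, c1 = c2 = 2, clamp ±6, 10 independent runs per dataset. None of
  these are given by the reference; they are the conventional defaults and
  all are configurable in `swarm_config()`.
* **Fitness.** `α·er + β·F/N` with α = 0.99, β = 0.01. `er` is the
  stratified 10-fold CV error of the wrapped classifier with the fold
  assignment fixed for the whole run (fold seed derived from the run seed,
  `bpso_fold_seed()`), making fitness deterministic within a run. The empty
  mask is pinned to fitness 1.0 without calling the classifier. Equal
  fitness prefers fewer features, then the lexicographically smaller mask;
  otherwise the incumbent pbest/gbest is kept.
* **Wrapped classifier.** Unstandardized euclidean 5-NN by default: small
  enough k to track local structure, large enough to smooth single-point
  noise, and its additive distance lets per-feature distance matrices be
  precomputed once per run — with per-mask memoisation, a 10 × 100 swarm on
  274 × 31 data runs in well under a minute on one CPU.

`exhaustive_best_subset()` enumerates all nonempty subsets (guarded to
N ≤ 12) under identical folds and tie-breaks, providing the independent
optimum that the swarm is tested against.

## The synthetic generator: what it emulates, and what a green test means

The motivating dataset is not public, so `generate_dataset()` produces
tables with the *documented* structure: 274 samples; positive fraction
125/274; Caucasian fraction 151/274; female fraction 118/274; age
truncated-normal with mean 50 and sd 14 on [19, 96] (the study describes age
as normally distributed around 50 and reports ages 19–96). Labels are
Bernoulli draws; planted features carry a class-conditional Gaussian shift
equal to the configured effect size (optionally modulated per demographic
group, which makes grouped analyses genuinely better and is how the
grouping-benefit property is tested); nominal features threshold a latent
Gaussian at equal-frequency cut points, preserving class dependence for
planted nominal columns; missingness is MCAR per cell, the simplest
mechanism consistent with the imputation rules. The planted set defaults to
the five severity features — RDI, the REM/NREM/supine AHIs, lowest SaO2 —
with standardized effect 1.5: severity indices are near-definitional for
OSA, so a strong planted signal there is the realistic stated world.

Two documented tensions in the source description were resolved once:

* The prose describes 620 patients while every experimental table sums to
  274; the generator defaults to 274 with the tables' proportions.
* An age centred at 50 cannot reproduce the reported 109/165 age-group
  split (that would need a mean near 53.6); the stated "around 50" wins and
  the generated split is close to even.

What the generator does **not** emulate: feature-feature correlations beyond
the planted structure, realistic marginal scales (non-demographic numerics
are left on the latent unit scale, which is immaterial after min–max
normalization), non-random missingness, and any physiological time series.
A green downstream test therefore establishes that the *algorithms* behave
as specified on data with the documented marginal structure — not that the
package reproduces clinic-grade accuracy values, which is impossible without
the clinic's data.

### Known limitation: wrapper overfitting at this sample size

With n = 274, one flipped out-of-fold prediction changes the fitness by
0.99/274 ≈ 0.0036, while the parsimony term charges only 0.01/31 ≈ 0.0003
per feature. Any noise feature that flips a single CV prediction by luck is
therefore worth keeping, and a 1000-mask search reliably finds several. The
practical consequence, visible in the acceptance suite: the selected subset
essentially always contains the planted features and clearly beats random
subsets of the same size, but it also carries a handful of chance features,
so exact support recovery (high Jaccard with the planted mask) is *not*
achieved at these weights and this sample size. The reference study's own
best masks keep 11–18 of 31 features, consistent with this analysis. Users
who need tighter supports should raise β, enlarge n, or aggregate selection
frequencies across runs (`selection_frequency()`) rather than trusting a
single best mask.

## Numerical conventions, in one place

| Situation | Convention |
|---|---|
| `max == min` in min–max scaling | normalized value 0 |
| Empty candidate mask | fitness 1.0, classifier not called |
| Equal fitness | fewer features, then lexicographically smaller mask; incumbent kept on full ties |
| Tied kNN vote | training majority class (label 0 if balanced) |
| Zero distance under 1/d or 1/d² weights | exact-match neighbours take the whole vote |
| Zero-variance column under z-scoring or correlation distances | column ignored with a warning |
| Zero-denominator metric | reported as 0 and listed in `undefined` |
| All paired differences zero (Wilcoxon) | degenerate, p = 1 |
| Wilcoxon branches | exact enumeration n ≤ 15, tie- and continuity-corrected normal beyond |
| Epworth score outside 0–24 or fractional | error |

## Reproducibility

Every stochastic operation takes an explicit integer seed, restores the
caller's RNG state, and derives child seeds (fold assignment, per-run
swarm seeds, per-group streams) through a fixed integer map, so
`run_experiment()` bundles are identical across invocations with the same
configuration. The per-iteration gbest trace is monotone non-increasing by
construction, and a recorded best mask's accuracy can be re-derived from
scratch from its run seed alone — both are asserted in the test suite
rather than claimed here.
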