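---
title: "Random-forest classification, selection and relation analysis for LC-MS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-forest classification, selection and relation analysis for LC-MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfmetab)
```

# Scope

`rfmetab` implements a complete random-forest workflow for untargeted
LC-MS metabolomics feature tables: preprocessing (adduct consolidation,
prevalence filtering, iterative forest imputation, batch-wise
autoscaling), multi-level classification with case-weighted forests and
probability machines, all-relevant feature selection with Boruta and with
Surrogate Minimal Depth (SMD), and the analysis of feature relations via
the mean adjusted agreement of surrogate splits — including hierarchical
relation heatmap clustering and the merging of features that stem from
the same metabolite (adducts and in-source fragments).  A synthetic
feature-table generator with known ground truth makes every stage
testable end to end.

The workflow is motivated by multi-level food-authentication studies of
white asparagus, where a single LC-MS feature table is classified both by
geographical origin (5 imbalanced classes, 317 samples) and by botanical
variety (4 classes on a 150-sample subset), and where relation analysis
of the selected features reveals groups of biologically related
metabolites.  Reference confusion tables from such a study ship with the
package (`reference_confusion()`) and anchor the evaluation code.

# The forest engine

Trees are binary Gini classification trees.  Each tree is grown on a
bootstrap sample of size `n` drawn *with replacement* with per-sample
probabilities proportional to the case weights; with
`case_weight_mode = "inverse_class_frequency"` (the default) a sample of
class `c` has weight `1 / (k n_c)`, so every class contributes the same
expected mass to each bootstrap sample and rare classes are oversampled.
At each node `mtry` candidate features are drawn without replacement;
thresholds are evaluated at midpoints between consecutive distinct sorted
values and the split maximizing the weighted Gini decrease is realized.
Nodes are split while they are impure and at least
`max(2, min_node_size)` samples large.  Defaults follow the study
parameterization for LC-MS tables: `ntree = 10000`,
`mtry = floor(p^(3/4))` (138 for `p = 718`), `min_node_size = 1`, and
`s = floor(0.05 p)` surrogate splits (35 for `p = 718`).

Exact gain ties between candidates are resolved by keeping the first
candidate in the (random) draw order.  Ties are frequent at small nodes,
and any position-based rule would prefer whichever features happen to sit
in low columns; that preference would bias both the corrected importance
(actual columns precede their pseudo copies) and the SMD null
calibration (real features precede the appended null copies).  The
draw-order rule makes the tie winner uniform among the tied candidates
while remaining fully reproducible from the seed.  Each tree derives its
own RNG stream from `(seed, tree index)`, so results do not depend on
execution order.

## Probability machines

With `mode = "probability"` the forest is used as a probability machine:
each leaf stores its class proportions and `predict_proba()` averages
them over trees (restricted to trees where a sample is out-of-bag with
`oob_only = TRUE`).  Rows sum to one by construction.  Hard
classification (`predict()`) instead lets each tree vote its leaf
majority; ties break to the lowest class index.

## Corrected impurity importance (AIR)

Raw Gini importance is biased toward features with many possible split
points.  The corrected measure draws one row permutation per forest and
gives every feature a *pseudo copy* whose values are looked up through
that permutation.  The candidate pool at each node doubles; pseudo
features compete for splits and are genuinely split on when they win.
The importance of a feature is the split-gain credit earned by its actual
values minus the credit earned by its pseudo copy.  For a feature
unrelated to the labels the two columns are exchangeable through the
whole growing process, so the expected importance is exactly zero; the
test suite checks this within two standard errors on pure noise.  Two
implementation details matter and were validated against an independent
implementation of the same measure: the permutation must be drawn per
forest (per-tree permutations let a feature's fixed sampling noise
persist across trees while pseudo noise is redrawn and averages out,
inflating actual features by several standard errors), and gain ties must
not be broken by column position.  Forests grown with
`importance = "air"` are importance sources only; prediction and
surrogate analysis on them are blocked.

## Surrogate splits and adjusted agreement

At every internal node (when `s > 0`) the engine records up to `s`
surrogate splits: for each feature other than the primary splitter, the
threshold and direction (children may be swapped) that best mimic the
primary left/right assignment.  Quality is measured by the adjusted
agreement

$$\mathrm{adj} = \frac{A - \mathrm{maj}}{1 - \mathrm{maj}},$$

where $A$ is the fraction of node samples routed like the primary split
and $\mathrm{maj}$ is the majority-rule baseline.  A perfect mimic (or a
perfectly anti-correlated feature, via the direction flip) scores 1; a
feature no better than the baseline scores $\le 0$ and is not stored.
Surrogate ranking ties use a per-node random key, for the same reason as
the split ties above.

# Feature selection

## Boruta

Each run appends one freshly permuted *shadow* copy per undecided feature
(at least five shadows), fits a corrected-importance forest on the
augmented table, and scores a *hit* for every undecided feature whose
importance exceeds the maximum shadow importance.  After each run a
two-sided exact binomial test (success probability 0.5) on the
accumulated hit counts confirms features in the upper tail and rejects
them in the lower tail at the configured level (default 0.01, as in the
study's parameter table); rejected features leave the model.  The loop
stops when nothing is undecided or after `max_runs` (default 100);
survivors are tentative.  No multiple-testing correction is applied by
default — the stated confidence level is taken as the operative
per-feature level — but a Bonferroni switch is available.

## Surrogate minimal depth

A feature's minimal depth in a tree is the smallest depth at which it
appears *either as the primary splitter or in a stored surrogate list*;
features absent from a tree are assigned that tree's maximal node depth.
SMD is the mean over trees: low values mean important, and features that
only ever mimic other features' splits — adducts of the same metabolite,
members of a correlated block — are still credited.  `smd_select()`
appends `min(p, 100)` permuted null copies to the table, fits one
surrogate forest on the augmented table, and confirms the real features
whose SMD falls below a threshold estimated from the null copies.  The
default rule is the null-copy mean (a deliberately inclusive,
all-relevant threshold consistent with SMD's purpose); a null-quantile
rule (e.g. 5%) is available where a calibrated false-positive level is
wanted, and the test suite verifies that its realized level on pure noise
is near nominal.  The threshold rule is a design choice of this package:
the study names the method but not the rule, and the original
publication's analytic threshold depends on internals of its
implementation.

# Relation analysis

For an ordered pair (i, j), the mean adjusted agreement `M[i, j]`
averages i's recorded surrogate adjusted agreement over *all* nodes of
the forest where j is the primary splitter; nodes where i was crowded out
of the stored top-`s` list contribute zero, which keeps the estimator an
average over a fixed node set.  `M[i, j] = 0` when j never splits.  The
matrix is directed; heatmaps and clustering use the symmetrized view
`S = (M + t(M)) / 2` with the diagonal set to 1 by convention, since the
Ward/Euclidean clustering needs a coherent row space and the asymmetry
carries no additional grouping information.  The directed matrix is
retained in all outputs.

Two design recommendations follow from the estimator's behavior, both
verified in the test suite:

* **Relation forests should use large terminal nodes.**  At a two-sample
  node essentially any feature can mimic the primary split, so adjusted
  agreements at tiny nodes are noise; with `min_node_size = 1` the node
  count is dominated by such nodes and the relation signal of even
  near-duplicate features (correlation 0.98) averages around 0.7.  With
  terminal nodes of order n/3 the same pairs score 0.85–0.95 and
  same-metabolite adduct triplets are recovered almost perfectly at a
  merge threshold of 0.8.
* **`s` should cover the expected block size.**  The default
  `s = floor(0.05 p)` matches the study scale (35 surrogates for 718
  features, blocks of 2–3), but a scaled-down analysis must scale `s` to
  the block size or partners crowd each other out of the stored list.

`merge_features()` thresholds `S` and returns the connected components of
size two or more; raising the threshold never enlarges a component.  The
companion `pearson_relation()` computes absolute Pearson correlations so
relation and correlation heatmaps are directly comparable; the test suite
includes a construction (a feature driving the outcome through its
magnitude, paired with its square) where the relation links outcome
partners that correlation cannot see.

# Preprocessing

The stage order is fixed: adduct consolidation, prevalence filter,
imputation, batch-wise autoscaling.

* **Adduct consolidation** keeps, within each annotated adduct group, only
  the feature with the highest mean intensity across samples (missing
  cells ignored).  "Highest intensity" is interpreted as the highest
  *mean* — robust and deterministic where a per-sample rule would not be.
  Features labelled as ammonium adducts are never merged, reflecting the
  binning ambiguity of ammonium adducts in positive-mode LC-MS; tables
  without annotations pass through unchanged.
* **Prevalence filter**: features observed in at least 80% of samples are
  kept; the boundary is inclusive (features present in *less than* 80%
  are excluded).
* **Imputation** follows the missForest scheme with regression forests
  (100 trees, `mtry = floor(sqrt(p))`): column-mean start, features
  visited in order of increasing missingness, each regressed on all
  others and its missing cells overwritten; iteration stops when the sum
  of squared changes of the imputed values first increases (the previous
  iterate is returned) or after `max_iter`.  Observed cells are never
  altered.  Imputation runs on the raw, unscaled table.
* **Batch-wise autoscaling** centers and scales every feature to mean 0
  and sd 1 (denominator n−1) *within each measurement batch*, which
  removes additive per-feature batch offsets exactly.  Constant columns
  become zero; single-sample batches are centered only, with a warning.

# The synthetic generator

`generate_dataset()` draws from an explicit latent model: one latent
intensity per metabolite per sample; each feature of a metabolite is
`sqrt(rho)` times the latent plus `sqrt(1 - rho)` independent noise, so
same-metabolite features have pairwise correlation `rho`
(`within_metabolite_corr`); informative metabolite groups receive
additive class-mean shifts of `delta` in feature-sd units; per-feature
per-batch offsets (sd `batch_sd` feature-sds) emulate batch effects; and
missingness is Bernoulli per cell with a logit linear in the globally
standardized log intensity, so low-intensity *features* lose cells more
often — which is what makes the 80% prevalence filter meaningful.

The default specification mirrors the asparagus study design: 317
samples in 3 batches, origin classes 213/25/31/13/35, variety classes
56/23/42/29 on a 150-sample subset, 240 metabolites with 3 features each.
The informative groups mirror the reported cluster structure: shared
blocks separating groups of classes (the North-European origins; Greece
with Peru) plus small marker groups specific to single classes, so every
class is distinguishable in principle.  Effect sizes (delta 1.2–2),
`rho = 0.95`, a 10% base missing rate with slope 2, and batch offsets of
one feature-sd are modeling choices — the study reports none of these
quantities — fixed once at values a metabolomics practitioner would call
realistic.  The generator does not emulate retention-time drift,
censoring-type (left-truncated) missingness, heteroscedastic
technical replicates, or isotope patterns; m/z and RT metadata are
placeholders.  Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the algorithms under the stated model,
not performance on any particular real instrument's output.

# Pipeline, reproducibility and problem sizes

`run_pipeline()` executes, per label scheme: classification forest with
OOB confusion metrics, probability forest with per-class OOB probability
summaries, Boruta and SMD selection, overlap counts, and relation
analysis over the SMD-selected features — preprocessing once on the full
table, scheme runs on the subset of samples carrying that scheme's label.
A single global seed fans out into stage-specific derived seeds
(`derive_seed()`), and rerunning a configuration reproduces every output
byte for byte; a manifest records configuration, seeds and MD5 checksums.
Stage failures abort with a stage-named error and leave a failure marker
beside the partial outputs.

The test suite and the acceptance script exercise the full pipeline on a
scaled-down study-design analogue (317 samples, 60 metabolites × 3
features, 500-tree forests, 300-tree selection forests) and verify
qualitative reproduction of the study pattern — out-of-bag error well
below the no-information rate on both classification levels, correct
classes winning the probability medians, selection sets of the right
order of magnitude with majority overlap between the two selectors —
rather than any published number, which would require the original
feature table.  These sizes were chosen so a complete run takes about a
minute on one CPU; conclusions at full scale (10,000 trees, 718 features)
differ only in variance.

# Known limitations

* AIR forests cannot predict; a separate forest must be fit for
  classification or probabilities (the pipeline does this).
* Surrogates serve relation analysis and SMD; they are not used to route
  samples with missing values at prediction time (prediction requires a
  complete table).
* The "specificity" reported alongside confusion matrices is the
  column-wise diagonal fraction — numerically the positive predictive
  value — under the name used by the reference tables it reproduces.
* `merge_features()` is transitive by construction (connected
  components): chains of pairwise-similar features merge even when their
  end members are less similar.
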