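---
title: "Discovering compact mRNA signatures for lower urinary tract dysfunction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering compact mRNA signatures for lower urinary tract dysfunction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lutdsig)
```

## The problem

Bladder pain syndrome (BPS) and detrusor overactivity (DO) are lower urinary
tract dysfunctions whose diagnosis is clinical and often ambiguous. A small
QPCR panel of bladder-biopsy mRNAs — thirteen genes selected for exclusive
regulation in one phenotype — can in principle separate BPS, DO and control
tissue. The statistical difficulty is the cohort: about sixty biopsies,
imbalanced groups (14 controls, 28 BPS, 22 DO), and thirteen features. In
this regime a carelessly evaluated classifier is almost guaranteed to be
optimistically biased, so the package treats evaluation hygiene — stratified
repeated and nested cross-validation, fold-internal resampling, a random
baseline — as the core of the method rather than an afterthought.

`lutdsig` implements the whole path: ΔΔCt fold-change computation, the
exclusivity panel filter, an exploratory statistics battery, unsupervised
structure discovery, a 12-classifier × 3-oversampler supervised grid with
recursive feature elimination, multi-metric scoring, and the intersection of
supervised with unsupervised evidence into a final marker signature. A
seeded generator with planted ground truth stands in for patient data, so
every stage is testable end to end.

## The data model

Everything flows through a genes × samples matrix tagged with its unit
(`read_count`, `ct` or `log2fc`), a sample→group annotation, and per-gene
DEG tables (log2FC, p). Validation is strict: duplicated ids, missing
values, non-numeric cells and negative counts are typed errors. Nothing is
imputed — with thirteen genes and sixty samples, silent imputation would
visibly move every downstream statistic.

For QPCR input, `compute_log2fc()` normalises each gene's Ct to the
reference gene in the same sample (ΔCt), then to the control-group mean,
with the sign fixed so that positive log2FC means *higher* expression than
control (lower Ct = more template):

$$\mathrm{log_2FC}(g, s) = \overline{\Delta Ct}(g, \mathrm{controls}) - \Delta Ct(g, s).$$

Technical triplicates are expected to be aggregated upstream; the function
takes one Ct per gene and sample.

## Panel selection

`select_marker_panel()` keeps genes significant in the primary comparison
(|log2FC| > 0.5, p < 0.05, raw p-values) and *not* significant in the other
comparison under the same thresholds; absence from the other table counts as
not significant, since exclusivity is not formally defined anywhere we could
borrow from. The filter is monotone — tightening a threshold never adds a
gene — and manual additions (the DO-exclusive NRXN3 in the motivating
application) are tagged separately.

## Supervised engine

The multi-class problem is decomposed one-vs-one (`BPS_vs_Control`,
`DO_vs_Control`, `BPS_vs_DO`), positive class = disease of interest.
Partitioning is stratified: per-class shuffling with remainder chunks dealt
from opposite ends so fold totals balance (28/14 at k=3 gives folds of
14/14/14 with 9–10 positives each).

**Oversampling is fitted inside each training fold only.** This is the
load-bearing design decision of the whole engine: fitting a SMOTE-family
sampler before splitting leaks near-copies of test points into training,
which at these sample sizes produces large optimistic bias. The three
samplers (Borderline-SMOTE, SVM-SMOTE, random oversampling) equalise class
counts by appending synthetic minority rows; SMOTE-family rows are convex
combinations of two minority neighbours. The published SVM-SMOTE includes an
extrapolation branch; it is omitted here so that every synthetic point
provably lies on a segment between two minority parents, which is the
contract the tests verify. Borderline-SMOTE falls back to plain SMOTE
seeding (with a warning) when no point is in the danger zone — small
oversampled folds hit this case routinely and a hard error would abort
entire grids.

The classifier roster is LR, LDA, GNB, SVM, KNN, DTC, GP, RF, BC, ETC, GBC
plus a seeded stratified-random Dummy baseline; each is crossed with the
three oversamplers (36 configurations). None of the usual R classifier
packages are assumed: trees and their ensembles are a compact C++
variance-reduction builder (for 0/1 responses Gini and variance give the
same split ordering), the SVM is a primal squared-hinge model optimised by
L-BFGS (linear and RBF via the representer form), the GP classifier is
RBF-kernel label regression with the median-heuristic length-scale, and LDA
uses a Ledoit–Wolf-shrunk pooled covariance. The shrinkage matters: with
n ≈ 40 and p = 13 the classical pooled covariance is ill-conditioned, and
its discriminant weights are too noisy to drive feature elimination.

Standardisation (fit on the augmented training fold) is applied for
distance/margin learners (LR, SVM, KNN, GP); tree ensembles see raw values.

### Feature selection

`rfecv_select()` runs recursive elimination (step 1) for each of three core
estimators — LR, LDA, linear SVM — scoring every candidate feature count by
repeated stratified k-fold F1 and ranking features by fold-averaged,
unit-normalised absolute weights. Two development observations shaped the
defaults, both variance-reduction measures rather than tuning:

* a single 3-fold pass is far too noisy at n ≈ 40 to order features
  reliably; scores and rankings therefore average over the configured
  repeats (10 × 3 folds by default);
* weight-based elimination under weak regularisation is dominated by noise
  directions long before accuracy suffers, so inside the RFE the linear
  cores use a stronger penalty (C = 0.1) while LDA self-tunes through its
  Ledoit–Wolf shrinkage.

Two count-selection rules are exposed. The default `"1se"` rule picks the
smallest count within one standard error of the peak score: parsimonious,
and on an uninformative panel it collapses to the `min_features` floor
(three) with a `low_score` flag, raised when even the peak score fails to
beat the always-positive no-skill F1 (2p/(1+p)) by more than one standard
error. The `"peak"` rule is the reference RFECV behaviour (argmax mean CV
F1, ties to the smaller count); it retains redundant-but-informative genes
and is what the consensus stage consumes, where generous per-core selections
are pruned by intersection.

### Evaluation schemes

`evaluate_model_grid()` runs n × k repeated stratified CV (defaults 10 × 3);
`nested_cv_evaluate()` adds an inner 3-fold grid search per outer fold,
tuning by F1 on the outer-training portion only. Hyperparameter grids are
small published defaults (log-spaced C, SVM kernel ∈ {linear, RBF}, KNN
k ∈ {3,5,7}, tree depth ∈ {3,5,∞}, ensembles fixed at 100 trees). Every
result carries an audit log of fold indices; the tests machine-check that no
outer-test index ever appears in an inner split and that train/test
partitions are disjoint. Identical config + seed reproduces every table
bitwise.

Seven metrics are computed per fold for the positive class — F1, Accuracy,
Balanced Accuracy, Precision, Recall, Average Precision, ROC-AUC — and
aggregated as mean ± sd. Models are ranked by mean F1 (ties: cumulative
score, then id). The cumulative performance score places the seven means on
a radar polygon in the frozen canonical order and takes the area ratio to
the unit polygon:

$$\mathrm{MLcps} = \frac{1}{M}\sum_{i=1}^{M} m_i\, m_{i+1}, \qquad m_{M+1} = m_1,$$

which is 1 iff all metrics are 1, 0 if all are 0, and c² for a constant
vector c. The published score's exact formula is not recoverable from the
sources available to this package (its companion software defines it); the
polygon-area reading matches the only operational description available —
the shaded spider-plot area — and is invariant under cyclic rotations but
not arbitrary permutations, hence the frozen order. Whether the original
uses metric sds as well as means is unknown; means only are used here.

## Unsupervised arm

PCA treats samples as observations on centred, scaled genes; per-PC variable
contributions are `100·loading²/Σloading²`. Hierarchical clustering defaults
to average linkage with one-minus-Pearson distance for count heatmaps and
Euclidean distance for QPCR log2FC (the motivating study fixes the metric
only for the former; the latter is a package choice, configurable).
k-means uses 25 seeded restarts; the elbow diagnostic reports the WSS curve
over k = 2..7 plus an advisory suggestion at the maximal second difference,
flagged low-confidence when the curvature is shallow (< 20% of the first WSS
drop) — the elbow is a visual tool and the full curve is always exported.
Cluster-transition tables (clustree-style) count sample flow between
consecutive k. Mahalanobis distances from a 3-marker centroid use the sample
covariance of that subspace; singular covariance is an error (no silent
regularisation).

## Consensus signature

Per task, the intersection of the three core estimators' peak-rule RFE
selections forms the supervised candidate set. The unsupervised candidates
are the union of the top `min_features` contributors of PC1 and PC2 plus the
top contributors of a k-means between-cluster variance share, with k taken
from the elbow suggestion (mirroring the elbow → k-means sequence of the
unsupervised analysis; the share ranking is driven directly by cluster-mean
separation and stabilises the PCA-only route). The consensus intersects the
disease tasks' supervised sets with the unsupervised set and finally keeps
only genes whose mean expression is elevated in the disease group — the
biological reading of the markers rests on elevated expression, and the
filter is switchable off.

The pipeline-level `top_n` default is `min_features` (3), not the
operation-level default of 2: a 2-per-dimension cap cannot ever return a
3-gene signature in full, while 3 aligns the unsupervised cap with the
supervised selection floor. This was fixed a priori, before any recovery
measurement, and not revisited.

## The synthetic world

`generate_qpcr_like()` draws `value(g, s) ~ Normal(mean(g, group(s)), sd)`
with control means 0 — log2FC values in the motivating cohort were
normally distributed, so a Gaussian world is the faithful emulation. The
default direction matrix encodes the reported regulation pattern (eight
genes up in BPS; FAT1 up in BPS/down in DO; AIM1 down in both; FAM83A down
in BPS; NRXN3 up in DO; MFAP5 null) at effect size 1.5 log2 units and noise
sd 1.0. The group sizes (14/28/22) are the cohort's. The effect size and
noise sd are calibration constants of this package — chosen once so that
the best models clearly beat the random baseline while the problem stays
non-trivial — and are not values reported for patients. Genes are
independent by default (an equicorrelation option exists because real
marker panels are correlated, but no covariance values are available to
copy). `generate_count_like()` produces negative-binomial counts for the
NGS-flavoured tests. Presets: `paper-qpcr`, `planted3` (only TPPP3, FAT1,
NCALD up in BPS — the planted signature for recovery tests), `null`.

What a green recovery test establishes: under independent Gaussian noise at
the stated effect size, the pipeline's selection and consensus machinery
finds exactly the planted markers in most draws. What it does not
establish: performance under correlated markers, batch effects, outliers,
or non-Gaussian QPCR noise — none of which the generator emulates.

## Known limitations and honest failures

On pure-noise data the acceptance criterion "every non-dummy model's
nested-CV mean F1 within 0.1 of the Dummy baseline" fails structurally, and
the package does not paper over it. With the disease as the majority class
(28 of 42), label-independent strategies span F1 from ≈ 0.56 (stratified
50/50 randomness — the Dummy trained on balanced, oversampled folds) to 0.80
(always-positive). Nested CV tunes by F1, which legitimately pushes models
toward majority voting on noise; oversampling additionally biases spatial
classifiers toward the class with more unique training loci. The same gap
reproduces in an independent reference stack. The leakage question the
criterion is really asking is answered by prevalence-robust audits that do
pass: ROC-AUC stays within 0.1 of 0.5 for every model, no model beats the
no-skill F1 ceiling, and the fold-index audit log shows no contamination.

Other boundaries worth knowing: Shapiro–Wilk is limited to 3 ≤ n ≤ 5000;
z-scores are undefined for constant genes (error, not NA); z = 0 is called
Low (a closed boundary chosen for determinism, measure-zero on continuous
data); sample (n−1) sds are used throughout; the ECDF uses the weak
inequality P(X ≤ x); KW post-hoc comparisons are rank-sum tests with
Benjamini–Hochberg adjustment (the original's post-hoc procedure is
unnamed); and the aggregated three-class predictor is deliberately out of
scope — each pair is analysed separately.
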