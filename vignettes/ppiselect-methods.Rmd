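---
title: "Methods: sequence-only feature selection for protein-protein interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-only feature selection for protein-protein interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiselect)
```

## The problem and the model

Whether two proteins physically interact is expensive to determine
experimentally, and most computational predictors either need structural
information or behave as black boxes. `ppiselect` implements a deliberately
transparent alternative built on a physicochemical-similarity hypothesis:
every protein is summarized by a vector of physicochemical descriptors
computed from its primary sequence alone, every *pair* of proteins by the
per-feature difference of those vectors, and interaction prediction becomes
ordinary supervised binary classification on those difference vectors. The
scientific payoff is not the classifier itself but the *selected features*:
which physicochemical differences carry the interaction signal.

The workflow has four stages, each a module of the package:

1. **Descriptors** (`compute_descriptors()`): amino-acid composition (AAC),
   dipeptide composition (DPC), Moran autocorrelation over property scales,
   pseudo and amphiphilic pseudo amino-acid composition (PAAC/APAAC), and
   composition-transition-distribution encodings (CTD), including solvent
   accessibility.
2. **Pair space** (`fit_normalization()`, `build_design_matrix()`): min-max
   rescaling of each feature to [0, 1], then per-pair difference vectors.
3. **Selection** (`select_features()`): bagged L1-penalized regression
   ("LASSO") or linear-SVM fits across stratified shuffled cross-validation
   folds; only features with non-zero coefficients in *every* fold survive.
4. **Evaluation** (`evaluate_baseline()`): a linear SVM on the selected
   features, scored by Accuracy, Recall, F1 and Matthews correlation (MCC)
   averaged over fresh 80/20 stratified folds.

## Descriptor definitions and conventions

**DPC.** For a sequence of $N$ residues over the 20 standard amino acids
there are $N-1$ overlapping adjacent pairs and $20 \times 20 = 400$ possible
dipeptides; each component is
$\mathrm{DPC}(i) = \#\{\text{occurrences of dipeptide } i\} / (N-1)$,
so the 400 components lie in $[0,1]$ and sum to 1.

**Moran autocorrelation.** For a per-residue property $M_1,\dots,M_N$ with
mean $\bar M$,
$$
\mathrm{Moran}(d) =
\frac{\tfrac{1}{N-d}\sum_{i=1}^{N-d}(M_i-\bar M)(M_{i+d}-\bar M)}
     {\tfrac{1}{N}\sum_{i=1}^{N}(M_i-\bar M)^2}.
$$
Features are named `MoranAuto_<Scale><d>`, e.g. `MoranAuto_Mutability27`
for residues 27 positions apart on the mutability scale. Conventions worth
stating: a zero-variance property returns 0 (the no-autocorrelation neutral
element, keeping feature matrices finite); scales are standardized to zero
mean and unit SD over the 20 letters before use, which changes nothing
mathematically because the statistic is invariant under affine rescaling of
the scale (property-tested); proteins shorter than the maximum lag are
excluded with a logged reason rather than zero-padded, because padding
fabricates signal. Eight property scales (mutability, steric parameter,
hydrophobicity, polarizability, solvation free energy, accessible surface
area, residue volume, polarity) ship as plain TSV resources with AAindex
provenance in their headers.

**PAAC/APAAC.** The package follows Chou's published closed forms (defaults
$\lambda = 10$ sequence-order tiers, weight $w = 0.05$, the defaults of the
propy toolkit whose conventions this package matches). Both normalize to
sum 1; APAAC's amphiphilic correlation terms are raw products and can be
negative, so non-negativity is asserted only for PAAC.

**CTD.** Seven properties, each partitioning the residues into 3 classes
(for solvent accessibility: buried `ALFCGIVW`, exposed `PKQEND`,
intermediate `MRSTHY`); 3 composition + 3 transition + 15 distribution
features per property. Distribution percentiles use the
`max(1, floor(q * count))` occurrence convention.

## Pair representation

Features are first rescaled by $\hat z = (z - z_{\min})/(z_{\max} -
z_{\min})$ so every property enters with similar weight. The difference
vector of a pair is $A - B = (A_1 - B_1, \dots, A_n - B_n)$. Two open design
points were resolved as follows:

* **Absolute vs signed differences.** The default is the absolute value
  $|A_j - B_j|$: interaction is a symmetric relation and the ordering of a
  pair in an input table is arbitrary, so a signed encoding would make the
  design matrix depend on file row order. Signed mode is retained behind
  `mode = "signed"` for fidelity experiments.
* **Normalization scope.** `fit_normalization()` records which protein set
  defined the limits; in the packaged pipeline the limits are fit once on
  the full proteome under analysis. When parameters are applied to proteins
  outside the fitted set, values are clipped into [0, 1]. Degenerate
  features ($z_{\max} = z_{\min}$) are dropped before modeling — constant
  columns carry no information and break standardization.

## Selection: bagging by fold intersection

Both selectors standardize features to mean 0, SD 1 (population-SD
convention, so a two-point column $\{1,3\}$ maps exactly to $\{-1,1\}$),
draw `n_folds` stratified shuffled 80/20 splits, choose the regularization
strength by grid search (one search over the fold ensemble, scored by mean
validation accuracy), then refit on every fold's training side at the
chosen value. The grid winner is the most regularized value whose accuracy
is statistically indistinguishable from the best — within one per-fold
standard deviation of the maximizer's accuracy, a one-SE-style rule whose
scale is honest about fold dependence (shuffled folds share most of their
training data, so an SE divided by $\sqrt{n_\text{folds}}$ would overstate
precision). Exact ties are the degenerate case. Without this rule a
no-signal dataset gets its regularization chosen by noise — maximizing over
$G$ noisy grid points inflates the winning accuracy by roughly
$\mathrm{SE}\sqrt{2\ln G}$ — and the resulting dense fits are stable across
overlapping folds, so the consensus fails to empty under a permutation
null. With it, a null dataset collapses to the fully shrunk end of the
grid and an empty consensus, while any real accuracy gap easily exceeds
the radius.

* **LASSO** minimizes $\sum_i (y_i - w_0 - \sum_j w_j x_{ij})^2 +
  \lambda \sum_j |w_j|$ — squared error on the 0/1 labels, exactly the
  printed selection objective, not logistic regression. It is solved by
  coordinate descent (glmnet); the user-facing $\lambda$ is on the scale of
  that objective and converted internally to glmnet's per-observation
  parameterization, so $\lambda = 0$ reproduces ordinary least squares
  (tested against the closed-form solution).
* **Linear SVM** minimizes $\tfrac12\lVert w\rVert^2 + C\sum_i \xi_i$; the
  primal weights are recovered from the support vectors and oriented so a
  positive margin predicts interaction.

A feature is *selected* when its coefficient is non-zero in all folds; its
score is the mean signed coefficient across folds, so negative scores mean
that larger differences in that property make interaction less likely.

Two numerical choices here are the package's own:

* **SVM support threshold.** An SVM weight vector is dense, so "non-zero"
  needs a cut. A tiny relative threshold (say $10^{-6}\max_k |w_k|$) passes
  every feature in every fold and the intersection rule degenerates to "keep
  everything". The package instead counts a weight as selected when
  $|w_j| > \operatorname{mean}(|w|) + 2\,\operatorname{sd}(|w|)$: scale-free,
  adaptive to the weight distribution, and under a label-permutation null no
  feature clears the cut in every fold, so the consensus empties as it
  should.
* **Grids.** $\lambda \in 10^{-4}..10^{2}$ (13 log-spaced points) and
  $C \in 10^{-3}..10^{2}$ (11 points), both overridable. On the default
  synthetic data, cross-validated accuracy for the LASSO is still rising at
  $\lambda = 10$, so the grid extends a decade further; both grids bracket
  the operating points ($\lambda \approx 0.004$, $C = 0.1$) commonly
  reported for this procedure on real interaction data.

## Evaluation

`evaluate_baseline()` restricts the design matrix to the consensus
features, then for each of `n_folds` fresh stratified 80/20 splits (drawn
from a seed independent of the selection folds, since reusing selection
folds would leak fold structure into the estimate) standardizes with
training-side statistics, trains the linear SVM, and computes
$$
\mathrm{Accuracy} = \frac{TP+TN}{TP+TN+FP+FN},\quad
\mathrm{Recall} = \frac{TP}{TP+FN},\quad
F1 = \frac{2TP}{2TP+FP+FN},
$$
$$
\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
$$
on the held-out side, reporting per-fold values and their unweighted means.
MCC with a zero marginal factor is 0 by the standard convention (so a
constant classifier on balanced data scores MCC 0, accuracy 0.5). The
baseline kernel is linear, consistent with coefficient-based selection; an
RBF kernel is deliberately out of scope.

## What the synthetic generator emulates

Real interaction datasets for this method are balanced tables of labeled
pairs over a proteome. The generator reproduces exactly that structure with
a known signal channel so that recovery is testable without downloads:

* **Proteome.** `n_proteins = 300` sequences of 100-300 residues drawn from
  Swiss-Prot-like background residue frequencies. A random half are
  "signal" proteins sampled from a first-order chain whose transitions into
  the planted dipeptides (default `VV`, `KK`, `IK`, `EE` — two charged
  homopairs, a mixed charged pair and a hydrophobic homopair) are boosted,
  then rejection-checked (at most 1000 resamples) until each planted DPC
  component exceeds `enrichment_factor = 3` times its background
  expectation. Rejection keeps sequences statistically natural aside from
  the planted marginal shift; explicit dipeptide insertion would not.
* **Labels.** For a candidate pair, let $s$ be the summed absolute planted
  DPC difference. Interaction probability is
  $\operatorname{logit}^{-1}(\alpha - \beta z)$ with $z$ the standardized
  $s$ and $\alpha$ calibrated so the marginal positive rate is 0.5; classes
  are then down-sampled to exact balance. The sign is the similarity
  hypothesis: pairs *differing less* in the planted compositions interact
  more. $\beta$ is placed on the standardized score so that it is
  dimensionless and comparable across configurations: $\beta = 0$ is an
  exact null, the default $\beta = 6$ gives an oracle (Bayes) accuracy
  around 0.92-0.94, and $\beta = 50$ makes labels nearly deterministic.
  `bayes_accuracy()` reports the oracle accuracy of thresholding the true
  linear predictor, an upper bound for any classifier trained on these
  data.

What the generator does **not** emulate: real proteome length
distributions, domain architecture, network topology (hubs, degree
distributions), or correlated descriptor families beyond what the planted
Markov shift induces. Passing recovery tests therefore shows the selection
machinery works when the signal channel is as claimed; it does not certify
performance on any real interactome.

## Problem sizes and determinism

The packaged experiments run at desk scale as the package's own protocol:
recovery experiments use the default generator (300 proteins, 600 balanced
pairs, 400 DPC features) with 10 selection folds over 10 seeds per method;
evaluation checks use 15 folds, matching the reporting convention of the
fold-averaged metrics. Every stochastic step (proteome, pairs, folds) flows
from an explicit integer seed, and identical (data, config, seed) inputs
reproduce byte-identical selection and evaluation results — this is
asserted in the test suite.

## Known limitations

* The LASSO selector regresses squared error on 0/1 labels, as specified by
  the printed objective; a logistic variant would weigh boundary pairs
  differently and is not provided.
* Consensus-by-intersection is conservative: a feature missing from a
  single fold is discarded, so weak-but-real features are traded away for
  false-positive control. Fold counts much larger than ~20 empty the
  consensus on noisy data.
* Descriptor families beyond the six shipped (e.g. quasi-sequence-order,
  Geary or Moreau-Broto autocorrelation) are not implemented.
* The pair representation is the per-feature difference only; concatenation
  encodings and kernel similarity measures are out of scope.
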