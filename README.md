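# ppiselect

Sequence-only feature selection for protein-protein interaction (PPI)
prediction.

Most PPI predictors either require structural or genomic context, or are
black boxes that predict without explaining. `ppiselect` is for
computational biologists who want the opposite trade-off: a transparent
pipeline that represents each protein purely by physicochemical descriptors
of its primary sequence, represents each protein *pair* by the per-feature
difference of those descriptors, and then asks — with a deliberately
interpretable model — *which physicochemical differences carry the
interaction signal*.

## The method in brief

For a protein of length $N$ over the 20 standard amino acids the package
computes descriptor families including the dipeptide composition

$$\mathrm{DPC}(i) = \frac{\#\{\text{occurrences of dipeptide } i\}}{N-1},
\qquad i = 1, \dots, 400,$$

Moran's autocorrelation of a residue property $M$ at lag $d$,

$$\mathrm{Moran}(d) =
\frac{\frac{1}{N-d}\sum_{i=1}^{N-d}(M_i-\bar M)(M_{i+d}-\bar M)}
     {\frac{1}{N}\sum_{i=1}^{N}(M_i-\bar M)^2},$$

plus amino-acid composition, pseudo / amphiphilic pseudo amino-acid
composition and composition-transition-distribution encodings. Each feature
is min-max rescaled, $\hat z = (z - z_{\min})/(z_{\max} - z_{\min})$, and a
pair $(A, B)$ becomes the difference vector $A - B$ (absolute by default).

Feature selection bags an L1-penalized regression
($\sum_i (y_i - w_0 - \sum_j w_j x_{ij})^2 + \lambda \sum_j |w_j|$) or a
linear SVM ($\tfrac12\lVert w \rVert^2 + C \sum_i \xi_i$) over stratified
shuffled cross-validation folds with a grid-searched regularization
strength; a feature is kept only if its coefficient is non-zero in **every**
fold. A baseline linear SVM on the selected features is then scored by
Accuracy, Recall, F1 and the Matthews correlation coefficient (MCC),
averaged over fresh 80/20 folds.

A synthetic-data module generates balanced pair sets over a simulated
proteome in which a known set of dipeptide-composition differences (default
`VV`, `KK`, `IK`, `EE`) drives interaction through a calibrated logistic
model, so selection recovery and evaluation calibration are testable end to
end with no external data.

## Worked example

Simulate a dataset with a planted dipeptide signal, run the pipeline, and
inspect what was selected:

```r
library(ppiselect)

cfg <- synthetic_config(seed = 42)      # 300 proteins, 300 pairs/class
sim <- simulate_ppi_dataset(cfg)

feats  <- compute_descriptors(sim$proteins, descriptor_config(families = "DPC"))
design <- build_design_matrix(sim$pairs,
                              apply_normalization(feats, fit_normalization(feats)))

sel <- select_features(design, selection_config("lasso", n_folds = 10, seed = 1))
sel
#> Bagged LASSO feature selection
#>   folds:          10 (stratified shuffled, 80/20 split)
#>   regularization: 100
#>   consensus:      4 of 400 features
#>   top features:   DPC_VV (-0.111), DPC_KK (-0.096), DPC_EE (-0.0876), DPC_IK (-0.0699)

ev <- evaluate_baseline(design, sel, n_folds = 15, seed = 7)
ev
#> Baseline linear SVM on 4 selected feature(s), 15 folds
#>   Accuracy 0.934  Recall 0.919  F1 0.933  MCC 0.869

bayes_accuracy(sim)   # oracle upper bound of this generator
#> [1] 0.9216667
```

The selection recovered exactly the four planted dipeptides, all with
negative scores: pairs that *differ less* in those dipeptide compositions
are more likely to interact (the physicochemical-similarity hypothesis the
generator encodes). The fold-averaged accuracy of 0.93 matches the
generator's oracle (Bayes) bound of 0.92 to within fold noise, i.e. the
selected four-feature model extracts essentially all available signal. `autoplot(sel)` and
`autoplot(ev)` draw the ranked-score and per-fold-metric figures;
`tidy()`/`glance()` return the same information as tibbles.

A command-line wrapper covers the same stages for shell use:

```sh
exec/ppiselect all --out run1 --seed 42
exec/ppiselect compare-dipeptides --fasta run1/proteins.fasta \
    --ids syn0001,syn0002,syn0003 --dipeptides VV,KK,IK,EE
```

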