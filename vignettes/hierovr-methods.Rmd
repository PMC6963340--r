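---
title: "Grade-specific biomarker discovery with hierarchical one-vs-rest classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grade-specific biomarker discovery with hierarchical one-vs-rest classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bulk expression cohorts graded by tumour aggressiveness — the motivating
case is prostate cancer graded by Gleason score — pose a multiclass
classification problem with two unpleasant properties: extreme class
imbalance (a five-group cohort of ~100 patients may contain a 4-sample
group next to a 55-sample group) and extreme dimensionality (tens of
thousands of transcripts quantified as TPM). The goal is not only to
predict the grade but to attach a small transcript panel to *each* grade:
the features that tell that grade apart from all the others.

`hierovr` implements a greedy hierarchical one-vs-rest scheme for this
setting. Gleason scores map onto five groups (6 → 1, 3+4=7 → 2,
4+3=7 → 3, 8 → 4, 9 and 10 → 5), but the code discovers the class set
from the labels and never hard-codes five groups.

## The procedure

At each internal node of the hierarchy, every remaining class is
evaluated as a candidate positive class against the pooled rest:

1. **Rebalancing.** The binary training set is cleaned with the
   neighbourhood cleaning rule (a sample is removed when at least two of
   its three nearest neighbours carry a different class) and the minority
   class is then oversampled with SMOTE (each synthetic sample lies at
   `a + u(b - a)`, `u ~ U(0,1)`, between a minority row and one of its
   `k = 5` minority neighbours) until the classes balance.
2. **Hybrid feature selection.** All features are ranked by information
   gain, `IG(A, X) = H(A) - H(A | bin(X))`, computed on equal-frequency
   10-bin discretisations. The top 100 enter a forward mRMR wrapper: the
   candidate ordering balances set relevance
   `V = (1/|S|) Σ I(h, i)` against set redundancy
   `W = (1/|S|²) Σ I(i, j)`, and a candidate is kept only if it strictly
   improves the stratified cross-validated accuracy of a linear-kernel
   SVM on the current subset.
3. **Classifier comparison.** Gaussian naive Bayes and a linear SVM are
   fitted on the selected features of the rebalanced training fold and
   scored on the untouched test fold; pooled confusion counts over folds
   give the node's accuracy, sensitivity, specificity, F-measure,
   Matthews correlation and ROC area. The better kind is retained.

The class whose one-vs-rest evaluation has the highest cross-validated
accuracy (ties: sensitivity, then specificity, then the lower label) is
isolated, its samples are removed, and the procedure recurses. The last
two classes share a final direct binary node, so C classes always yield
C − 1 decision points. Isolating the most separable class first limits
how far its errors propagate down the tree. Prediction walks a sample
down the isolation order and assigns the first node that claims it.

Once a class is chosen, its node classifier is refit on all remaining
samples (rebalanced and re-selected on the full remaining set); CV is
used only for candidate scoring. A node reports two feature sets: the
refit selection its classifier actually uses
(`selected_feature_ids`), and the biomarker panel
(`panel_feature_ids`) — the refit selection united with the features
chosen across the winning candidate's training folds. Aggregating
selections over resampled fits is how panels are usually reported
(features that recur under perturbation are the credible candidates);
the operational classifier stays restricted to the refit subset.

## Leakage control

Three rules keep the evaluation honest, and the provenance tags produced
by the resampler make all three auditable:

* Resampling and feature selection are re-run inside every training
  fold; evaluation folds contain original samples only.
* The wrapper's internal cross-validation assigns folds over original
  rows only; a synthetic row joins an inner training set only when both
  of its SMOTE parents lie outside the inner evaluation fold.
* All selection statistics (the information-gain ranking and every
  mutual-information term of the mRMR objective) are computed on
  original rows. Interpolated rows have systematically shrunken
  variance, which would otherwise manufacture class relevance for
  uninformative features — in simulation, planted markers that occupy
  the top six ranks on original rows get pushed out of the top fifteen
  when synthetic rows are included.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `smote_k` | 5 | minority neighbours SMOTE may interpolate toward |
| `ncl_k` | 3 | neighbours in the cleaning vote (2-of-3 rule) |
| `target_ratio` | 1.0 | minority/majority ratio after resampling |
| `ncl_scope` | `majority_only` | which classes the cleaning rule may remove |
| `n_bins`, `method` | 10, equal-frequency | discretisation for all entropies |
| `top_k` | 100 | information-gain shortlist size |
| `max_features` | 15 | hard cap on a node's panel |
| `min_delta` | 0 | required CV-accuracy improvement (strict) |
| `inner_folds` | 5 | wrapper's internal stratified folds |
| `cv_folds` | 10 | outer folds for candidate scoring |

`ncl_scope` deserves a note. The cleaning rule is used here as a
*majority* undersampler. An unrestricted vote (`any_class`) is also
available, but in high dimensions nearest-neighbour votes are dominated
by noise directions and are majority-biased, so the unrestricted variant
strips most of the minority class (in a 55-vs-24 problem at 2000
features it removed 21 of the 24 minority rows), after which
oversampling degenerates to interpolating a handful of survivors.

`max_features = 15` matches the largest panel the method is expected to
report; `min_delta = 0` makes acceptance conservative: the wrapper stops
as soon as no candidate strictly improves the wrapped accuracy, so panels
stay small. The outer fold count is automatically reduced (with a
warning) when a class is smaller than the fold count — unavoidable when
a 4-sample class meets 10-fold cross-validation.

Eq.-level choices: the redundancy double sum includes the diagonal
self-information terms as written (a singleton's redundancy is `H(f)`);
`include_diagonal = FALSE` gives the common off-diagonal variant. The
relevance/redundancy trade-off is combined additively (`V − W`) rather
than as a quotient, avoiding division by near-zero redundancy.

## The synthetic-data generator

Because the cohorts this method targets cannot be bundled, the package
ships a generator that emulates their structure and makes every stage
testable:

* five classes with sizes 10/55/24/10/4 (the study imbalance, including
  a 4-sample class);
* 2000 transcript features by default (scalable toward the ~42,000 of a
  full transcriptome), each with its own baseline log2-TPM mean drawn
  from `N(3, 1.5)` — the transcriptome-wide spread — and sample-to-sample
  within-class noise of sd 0.5, typical bulk RNA-seq biological
  variability. The two scales are deliberately separate: collapsing them
  into one (every value iid from `N(3, 1.5)`) would give every
  transcript sample-to-sample noise as wide as the whole transcriptome
  spread, which no TPM matrix exhibits, and would drown any plausible
  marker effect;
* three planted marker transcripts per class, disjoint across classes,
  shifted by +2 log2 units within their class;
* 10% dropout zeros, applied independently.

What the generator does *not* model: library-size effects, batch
effects, gene–gene correlation beyond the planted markers, and
count-level noise (it produces TPM directly, log-normally, rather than
negative-binomial counts — the pipeline consumes normalised TPM, so
count-level fidelity buys nothing here). Passing tests therefore
demonstrate correct mechanics and recovery under idealised independent
features; they do not certify performance on real cohorts, where
correlated housekeeping structure and batch effects can mimic or mask
markers.

Two calibration facts shape what the tests can honestly assert. First,
dropout is the binding constraint on accuracy: zeroing 10% of a
marker's values inflates its within-class variance so much that even
classifiers trained on the *true* markers reach only ~87% hold-out
accuracy end-to-end at these settings (the measured oracle ceiling; at
within-class sd 0.75 the ceiling is ~82%, at 1.0 ~78%). Second, a class
with 4 samples is at an information-theoretic floor: its class entropy
(~0.24 bits) is inside the maximum-noise information-gain band of 2000
features, so no generator at these class sizes can make its markers
reliably outrank noise, and selection for that class is best-effort.

## Numerical choices

* Entropies are in bits; `0 log 0 = 0`; empty bins contribute nothing.
* Equal-frequency bin edges are the training-data quantiles; duplicate
  quantiles (common with zero-inflated TPM) are collapsed, so a feature
  may occupy fewer than `n_bins` bins; held-out values beyond the
  training range fall into the outermost bins.
* Neighbour ties (NCL and SMOTE alike) break toward the lowest row
  index; ranking ties break lexicographically by feature ID; equal-
  accuracy classifier kinds keep the first-listed kind. All randomness
  derives from one seed through a fixed affine fan-out, so identical
  (data, config, seed) rebuilds byte-identical model files.
* Naive-Bayes variances get a floor of `1e-9 × max(var)` so constant
  features cannot produce infinite densities; the SVM decision sign is
  fixed empirically after fitting so positive scores always mean the
  positive class.
* Fold metrics are aggregated by pooling confusion counts (matching
  correct-out-of-total overall accuracy); per-fold metrics are kept
  alongside. ROC areas use midpoint ranks for ties and are reported
  absent, never fabricated, when no decision scores exist.
* Models serialize to JSON (schema-versioned); classifier parameters are
  stored as plain numeric arrays, so a reloaded model predicts
  identically to the in-memory one.

## Problem sizes used in the shipped tests

Unit tests run on reduced instances (≤ 120 features, ≤ 44 samples) that
preserve the full structure — imbalance, a 4-sample class, dropout.
End-to-end recovery runs at the full default conditions (2000 features,
103 samples, 10 seeds) with 3 outer folds, a 50-feature shortlist and
the default 15-feature cap per node; matched held-out test sets reuse
the planted markers and baselines with fresh noise. These sizes are the
package's chosen test conditions; the method itself has no intrinsic
limits beyond memory.

## Known limitations

* The greedy wrapper cannot assemble complementary (XOR-style) feature
  pairs; the selection trace records the rejections.
* With `min_delta = 0` and a perfect intermediate accuracy the wrapper
  stops early by construction, so reported panels can be smaller than
  the full planted truth even when more markers exist.
* Small-class nodes (4 positives) have metrics that rest on very few
  samples; the fold reduction warning makes this visible.
* The per-node accuracy ceiling under 10% dropout is set by the
  classifiers' Gaussian/linear form, not by selection quality.
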