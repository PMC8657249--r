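---
title: "Stacked ensembles with correlation-based classifier removal: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensembles with correlation-based classifier removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Registry cohorts of cancer survivors are used to predict a binary clinical
event — here, the occurrence of a second primary cancer (SPC) — from a
modest number of mixed-type prognostic variables (staging codes, treatment
sequencing, radiotherapy dose, anthropometrics). Single classifiers each
capture part of the structure: linear models the additive effects, trees the
thresholds and interactions, instance-based learners the local geometry.
`stackprune` implements a stacked-generalization scheme built around one
idea: *ensemble only classifiers whose predictions disagree enough to be
complementary*, and afterwards aggregate their feature-importance rankings
into a single clinically readable list.

The pipeline is:

1. **Split** the cohort 60/40 into training and test partitions.
2. **Tune** each base classifier by random hyper-parameter search
   (`m` candidates, default 30) under repeated stratified k-fold
   cross-validation (default 10-fold, 3 repeats), selecting the candidate
   with the highest mean fold AUC. The minority class is upsampled to exact
   balance *inside each training fold only*.
3. **Eject** any learner whose out-of-fold (OOF) prediction vector contains
   missing values — it cannot enter the correlation analysis.
4. **Remove** redundant learners iteratively: compute the Pearson
   correlation matrix of the OOF probability vectors; while the largest
   upper-triangular entry exceeds a threshold (default 0.75), drop the pair
   member whose mean correlation to the other remaining learners is larger,
   and recompute on the shrunken matrix.
5. **Stack**: fit a logistic meta-classifier on the survivors' OOF
   probabilities. Its coefficients are the ensemble weights.
6. **Evaluate** on the held-out partition: confusion matrix at 0.5,
   accuracy, sensitivity, specificity, balanced accuracy
   $= (\mathrm{sens} + \mathrm{spec})/2$, and rank-statistic AUC.
7. **Rank features**: per-learner importances are converted to within-learner
   ranks (1 = most important), combined as a weighted rank sum with weights
   $w_j = |\beta_j| / \sum_k |\beta_k|$ from the meta-coefficients, and
   truncated at a knee point found by the best two-line least-squares fit.

## Why out-of-fold predictions

The meta-classifier is trained on OOF probabilities: for each training case,
the prediction used comes from a model whose training fold excluded that
case. Training the meta-model on refit-on-train predictions would reward
base learners for overfitting. The same OOF vectors feed the correlation
matrix, so "redundancy" is measured on honest predictions. Both choices are
the standard stacking prerequisite and require every learner to share one
fold assignment (`make_cv_folds()` + a shared `folds` object).

One ambiguity deserves a note: "prediction correlation" could also mean the
correlation of per-fold resampled *metric* values (the convention of some
ensembling toolkits). This package correlates the predictions themselves,
which is the literal reading; correlating n-vector predictions is also far
better determined than correlating k-vector fold metrics.

## The learner registry

The scheme is learner-agnostic; `register_learner()` accepts any
fit/predict pair with hyper-parameter sampling rules. The shipped registry
covers the classical roles with what a lean scientific R stack provides:

| name | role | tuned over | importance |
|------|------|-----------|------------|
| `lgr`  | logistic regression | — | \|standardized coefficient\| |
| `enet` | elastic-net logistic | alpha, lambda | \|standardized coefficient\| |
| `gam`  | spline GAM (the smooth-nonlinear role) | basis size, penalty inflation | permutation |
| `lda`  | linear discriminant | — | \|discriminant loading\| |
| `rda`  | shrinkage quadratic discriminant | pooling, spherical shrink | permutation |
| `knn`  | k-nearest neighbours (standardized) | k | permutation |
| `nb`   | Gaussian naive Bayes | variance smoothing | permutation |
| `cart` | Gini decision tree | depth, leaf size | impurity decrease |
| `bag`  | bagged Gini trees (the forest role) | trees, depth, mtry | impurity decrease |

Permutation importance is the AUC drop when one design column is shuffled,
averaged over repeats, evaluated on a seeded subsample (default 1500 rows)
because the contrast stabilises long before the full cohort is needed.
One-hot columns are summed back to their parent feature before ranking.

A back-propagation neural network role is deliberately absent: no maintained
implementation is available in the supported dependency set, and a hand-written
one would be the least trustworthy member of the bank. The registry is the
extension point if one becomes available.

## The synthetic cohort: what it emulates, and what a green test means

The real registry data this design targets is access-restricted, so the
package ships a generator whose *defaults are its stated world*: n = 27,455
with target prevalence 3365/27455 ≈ 12.3%, and fourteen mixed-type features
named and typed like the registry variables (staging ordinals, treatment
categoricals, continuous dose/BMI/node size). Labels are drawn
Bernoulli(sigmoid(intercept + signal + noise)) with the intercept calibrated
by root finding so the expected event rate hits the target exactly.

Six features carry signal; eight are pure noise. The signal is deliberately
split across components that different learner families see differently:

* linear: BMI (−0.30), sex (+0.35), clinical stage (+0.25),
  nodal levels I–III (+0.40), on standardized encodings;
* threshold: +1.3 × centred 1(lymph-node size > 3 cm) — invisible as a
  slope, easy for trees and smooths;
* interaction: +0.8 × (clinical stage × CTV_L dose, both standardized) —
  invisible to every additive learner; quadratic-discriminant, tree and
  nearest-neighbour learners can express it;
* logit-scale Gaussian noise, sd 0.5.

These weights were calibrated **once**, before the test suite was frozen, to
four target properties a scientist would demand of a realistic stand-in:
realized prevalence within one point of 12.3%; an oracle (true-linear-
predictor) AUC near 0.78, the performance regime typical of registry risk
models; an inter-learner OOF correlation structure in which only genuinely
redundant learners exceed 0.75 (duplicate linear pairs near 0.99, cross-family
pairs 0.4–0.7) so the removal scheme faces the situation it was designed for;
and six planted signals of comparable aggregated strength so the importance
curve bends near position six. An earlier linear-dominant weighting failed
the third property — every strong learner correlated above 0.86 with every
other, removal pruned all of them, and the ensemble degenerated — which is
itself an instructive boundary condition of the method, discussed below.

What the generator does **not** emulate: the real cohort's joint
distribution, missing data, measurement error, temporal drift, or censoring.
A green recovery test therefore establishes that the machinery finds planted
structure of realistic strength in clean data of the right shape — not that
it would rank the real registry's risk factors correctly.

## Numerical and procedural choices

* **Splits**: stratified by default (stable at 12% prevalence); plain random
  — the protocol-faithful mode — one flag away. Indices are 1-based.
* **Upsampling** duplicates minority rows with replacement until exact
  balance, only ever inside a CV training fold or a final (re)fit, never in
  a held-out fold or the test set. The meta-classifier's training rows are
  upsampled under the same rule: base learners trained on balanced folds
  emit probabilities calibrated to ~0.5 prevalence, and fitting the
  meta-model on the raw ~12% labels would push every ensemble probability
  under the 0.5 decision threshold (sensitivity would collapse to zero even
  while the AUC stayed high).
* **Tie-breaks**, all deterministic and logged: maximal correlation pair →
  lexicographic pair order; equal average correlations → lower CV AUC
  removed; equal aggregated importance scores → alphabetical; knee-point RSS
  ties (within float tolerance) → smallest split, flagged "no clear knee".
* **Threshold 0.5** with "≥ counts positive" for confusion matrices;
  configurable.
* **Metric rounding**: three decimals, half away from zero (0.7605 → 0.761).
* **Perfect separation** in the meta-fit falls back to a ridge-penalized
  logistic fit with a warning; aliased (duplicate) survivor columns get a
  zero coefficient, which leaves predictions unchanged.
* **Removal threshold ≥ 1** is accepted and simply disables pruning (no
  correlation can exceed it); this is how the "without removal" arm can be
  expressed in one configuration.
* **Direction labels** come from the tuned base logistic regression's
  coefficient signs, not from the meta-model: continuous/ordinal/binary
  features are signed, multi-level categoricals are labelled unsigned (one
  sign per level would be meaningless for a single bar).
* Features removed from the ensemble contribute nothing to the aggregated
  importance: only survivors hold meta-weights. The tuned logistic learner
  is still consulted for direction signs even when pruned.

## Known limitations

* The removal scheme optimises diversity, not accuracy: when *every* strong
  learner in a bank is mutually correlated above the threshold, the chain
  removes all but one of them and the surviving stack can trail the best
  single learner. The scheme presupposes a bank whose members are
  individually strong *and* family-diverse; composing such a bank is the
  analyst's job, not the algorithm's.
* More fundamentally, when the meta-classifier is fit honestly on
  out-of-fold predictions, a logistic meta-fit absorbs redundant
  (collinear) inputs on its own, so pruning can only discard information.
  In the package's acceptance simulations the with-removal ensemble is
  AUC-neutral at best against the without-removal ensemble (per-seed
  differences of 0.001–0.02 in either direction, with the no-removal arm
  slightly ahead on balance), even while both comfortably match or beat the
  best single base learner. The corresponding directional acceptance test
  is deliberately left failing rather than weakened. Where the removal
  scheme clearly earns its keep is interpretability and cost: the survivor
  set is small, diverse, and the importance aggregation is spread over
  genuinely different model families.
* Pearson correlation of probabilities is sensitive to each learner's
  probability calibration, not only to its ranking; two learners with
  identical rankings but different calibration curves correlate below 1.
* The knee point assumes the sorted importance curve is adequately described
  by two lines; importance curves with several regimes will truncate at the
  first strong bend.
* No probability calibration layer, no confidence intervals for AUC, no
  multi-class support, and no handling of censoring — the outcome is a plain
  binary label.
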