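---
title: "Deriving a blood-based response prediction score: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a blood-based response prediction score: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpscore)
```

## The clinical problem

Patients with locally advanced rectal cancer (LARC) receive preoperative
chemoradiotherapy (CRT) followed by total mesorectal excision. Pathologic
response is graded by the AJCC tumor regression grade (TRG): 0 (complete
response) to 3 (poor response). Good responders (TRG 0--1) have better
outcomes and are candidates for organ-preserving strategies, so a cheap
early predictor of response is clinically valuable. Routine blood panels
drawn before CRT and again 1--2 weeks after CRT starts are essentially
free; treatment-induced changes in leukocyte lineages (monocytes,
neutrophils, eosinophils) and platelets plausibly carry response
information well before restaging imaging.

`rpscore` implements the full derivation workflow for a compact linear
score of this kind -- the Response Prediction Score (RPS) -- together
with the published five-term instance of it:

```{r}
published_rps()
```

Higher scores predict the positive class, which throughout this package
is the **poor responder** (TRG 2--3). That orientation is implied by the
score's construction: its monocyte/neutrophil/platelet weights are
positive, early leukocyte counts are reported to be lower in complete
responders, and the lymphocyte-to-monocyte ratio enters comparisons with
a negative sign relative to the label. Because the convention is easy to
get backwards, it is encoded in exactly one place
(`derive_label()`: label 1 iff TRG $\ge$ 2) and every other function
consumes that label.

## The derivation pipeline

The workflow has five stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`.

### 1. Representative splitting (Kennard--Stone and Morais--Lima--Martin)

With a few hundred patients, a random 70/15/15 split can easily place
all of one region of feature space in the training set and none in
validation. The Kennard--Stone (KS) algorithm instead selects training
samples greedily: after standardizing all features, start from the two
mutually farthest samples, then repeatedly add the sample whose minimum
Euclidean distance to the already-selected set is largest. The selection
covers the feature space uniformly, and `kennard_stone()` is
deterministic (ties break to the lowest row index; the test suite checks
exact agreement with a brute-force greedy oracle).

Pure KS has almost no randomness, which defeats repeat-based stability
analysis. The Morais--Lima--Martin (MLM) variant restores it with a
*mutation* step: 10% of the KS-selected training rows (rounded) are
swapped one-for-one with uniformly chosen held-out rows. `mlm_split()`
implements the 70/15/15 contract (sizes are rounded fractions; a
200-row matrix gives 140/30/30 with exactly 14 swaps).

Two details are not pinned down by the algorithm's usual description
and are therefore explicit, configurable choices here:

* **Seeding.** "Start from the two mutually farthest samples" is the
  classic rule and the default (`init = "farthest_pair"`); a single-seed
  "largest mean distance" variant is available.
* **Carving tuning vs validation.** How the 30% remainder becomes
  tuning and validation sets is unspecified in the source method; the
  default runs a *second* KS pass on the pool (so both held-out sets
  are representative), with `pool_method = "random"` as the
  alternative. The mutation step runs before the carve.

Categorical features enter the distance as integer codes after
standardization -- a documented limitation, acceptable because the
categorical variables here are few and ordinal-ish.

### 2. Repeated benchmark

`run_benchmark()` repeats N times: derive a per-repeat seed from the
master seed (a counter-based scheme, so partial reruns reproduce),
draw an MLM split, and for every requested feature set and model kind
run feature selection, hyperparameter tuning and evaluation. The five
feature sets are the tumor-related clinical trio (distance from the
anal verge, CEA, tumor grade), the clinical set (trio plus age, sex,
clinical T/N -- the full clinical membership is an assumption, the
source enumerates only the trio), clinical + pre-CRT panel (17 CBC +
12 chemistry features), clinical + early-CRT panel (17 CBC features;
no chemistry is measured early), and clinical + both panels. Derived
indicators (NLR, PLR, LMR, PNI) are never model inputs; they are
competing baselines in the final comparison.

Feature selection is univariate on the *training rows only*:
Mann--Whitney U for continuous features, Pearson chi-squared for
categorical ones, retaining P < 0.1. It is skipped for the two
clinical-only sets (too few features; selection tended to empty them)
and for lasso (which selects internally) and the neural network
(which re-represents rather than selects). If selection empties a set,
the fit falls back to all features.

Six model kinds are supported: logistic regression (`stats::glm`),
ridge and lasso (`glmnet`), gradient boosting (`xgboost`), random
forest (`ranger`), and a two-layer neural network (`nnet`: one hidden
layer with logistic output -- "two-layer" counted as hidden + output).
Hyperparameters are chosen by tuning-set AUROC over small grids
(ridge/lasso: 7-point log-spaced penalty on $[10^{-3}, 10^3]$;
boosting: trees 50/200 x depth 2/3 x learning rate 0.05/0.1; forest:
trees 200/500 x depth 3/unlimited; network: 8/16/32 hidden units x
weight decay 0.1/0.01, decay standing in for early stopping, which
`nnet` does not provide). The grids are this package's declared
defaults; ties resolve to the simpler configuration. All features are
standardized with training-set centre/scale before fitting, and linear
coefficients are back-transformed to raw units
($\beta_\text{raw} = \beta_\text{std} / s$), so nothing downstream
depends on the standardization.

The benchmark also has a null-calibration mode
(`permute_labels = TRUE`) that re-permutes the labels independently in
every repeat -- the standard permutation null. This is the right way to
check harness bias: a *fixed* finite cohort, even one generated with no
feature--label dependence, realizes chance associations that persist
across splits of that same cohort, so mean validation AUROC on a fixed
null cohort legitimately deviates from 0.5. Under per-repeat
permutation it cannot.

### 3. Generalized importance and score-size selection

For a linear kind, each repeat $i$ yields a coefficient vector
$\beta_{ki}$ on raw units, with 0 for features that did not survive
selection. The generalized importance of feature $k$ is the plain
across-repeat mean

$$\bar\beta_k = \frac{1}{N}\sum_{i=1}^{N} \beta_{ki},$$

so the average encodes both magnitude and selection frequency.
`generalized_importance()` reports this raw-scale mean (it becomes the
score weight) together with the selection count and a sign-consistency
fraction, but **ranks** features by the mean *standardized* coefficient.
Ranking on raw units would compare "per cell/uL" against "per cm" --
dimensionally meaningless -- and the published five-term score is
itself ordered by importance yet not by raw magnitude (its distance
weight, 0.026172, is the largest raw coefficient but distance is listed
second), which is only consistent with importance being judged on the
standardized scale. The package therefore treats standardized magnitude
as the importance axis and raw-scale means as the weights.

The score size $K_o$ is chosen from the significance curve
(`select_score_size()`): for $K = 1, \dots, K_\max$ (default 10), build
the candidate score from the top-$K$ features and their raw weights,
evaluate it on the whole cohort, and test it between responder groups
with the Mann--Whitney U test. $K_o$ is the global arg-min of the
P-value curve, ties toward the smallest $K$ (the source narrates a
simplicity/power trade-off without a rule; arg-min with a
smallest-$K$ tie-break is the pinned one). A degenerate candidate
(all-equal scores) records P = 1 rather than erroring.

`sign_consistency_audit()` reports, per feature, the fraction of
selecting repeats whose coefficient sign agrees with the sign of the
mean -- a stable score feature should sit near 1. When the mean is
exactly zero the modal-sign fraction is reported instead.

### 4. Evaluation metrics

All metrics are pinned, deterministic conventions:

* **AUROC** (`auroc()`) is the tie-adjusted pairwise concordance
  probability (ties count 1/2), identical to the trapezoidal area over
  distinct thresholds; the suite checks exact agreement with exhaustive
  pair enumeration and with an independent ROC implementation.
* **AUPRC** (`auprc()`) integrates the precision--recall staircase with
  right-continuous *step* interpolation (linear interpolation in PR
  space is optimistically biased).
* The **optimal cut-point** (`youden_cutpoint()`) maximizes Youden's
  J = sensitivity + specificity - 1 over observed thresholds, ties to
  the lower threshold (the source applies an "optimal cut-point"
  without defining it; Youden is the pinned choice).
* **Mann--Whitney U** uses midranks and the tie-corrected normal
  approximation with continuity correction throughout (no exact
  small-sample path; at cohort scale the approximation error is far
  below the decision threshold). **Chi-squared** is Pearson without
  continuity correction.

### 5. Baselines and stratification

`compare_predictors()` computes AUROC against the poor-responder label
for every single blood feature, the pre-CRT NLR/PLR/LMR/PNI and the
early-CRT NLR/PLR/LMR (the early panel has no albumin, so no early
PNI), and the score. Predictors anti-correlated with the label are
re-reported as their negation with a "-" prefix, mirroring how an LMR
is conventionally flipped. `stratify_quartiles()` groups patients at
the score's empirical Q1/median/Q3 (linear-interpolation quantiles,
`stats::quantile` type 7) and tabulates TRG and downstaging outcomes
per group. Overall downstaging is ypT0-2N0 (the cohort is M0 by
population definition); T-/N-downstaging are strict decreases from the
clinical stage. No monotonicity is assumed for T-downstaging, whose
reported direction in the source runs against the TRG trend and may be
a typo.

## The synthetic cohort generator

The patient data behind the published score are not deposited, so every
stage is exercised on synthetic cohorts (`generate_cohort()`), and the
generator is first-class, tested code. Design:

* **Blood panels.** Counts are log-normal around standard adult
  reference medians (e.g. platelets 250 x 10^3/uL, neutrophils
  4200/uL, albumin 4.3 g/dL) with feature-specific log-scale spreads
  (eosinophils widest at 0.65). Simple physiologic coupling is kept:
  WBC is the sum of its differential, hemoglobin/hematocrit follow the
  red-cell indices, plateletcrit follows platelet count x mean platelet
  volume. Richer real-world correlation structure is a non-goal.
* **Early-CRT panels** are the pre-CRT values times a per-feature
  decline factor (lymphocytes 0.35, neutrophils 0.65, eosinophils 0.60,
  platelets 0.80 -- treatment-induced cytopenia, strongest for
  lymphocytes) times within-patient log-normal noise (sd 0.18).
* **Outcomes.** TRG is drawn from an ordinal logistic model on a latent
  predictor built from the planted standardized features, with
  thresholds calibrated on the realized predictor so the expected
  good-responder fraction equals the configured prevalence (default
  0.43 of roughly 272 patients). Pathologic ypT/ypN are sampled
  conditional on TRG so good responders downstage more often, and
  TRG 0 forces ypT0/ypN0. Missingness is optional and MCAR (the
  source's missing-data pattern is unknown), default 0.
* **Planted effects** (per SD, toward poor response): early monocyte
  +1.1, early platelet +1.0, early neutrophil +0.9, early eosinophil
  -0.9, distance from the anal verge +0.75. Magnitudes were fixed once,
  by pilot calibration, so that each planted feature's induced
  between-group difference stands clear of the spurious associations a
  fixed 272-patient cohort realizes by chance -- the property that
  makes the planted ground truth reliably recoverable by the full
  pipeline across seeds. Distance is deliberately the weakest: it
  belongs to every feature set, and a dominant distance effect would
  make even clinical-only models predictive. The resulting ridge
  validation AUROC on clinical + early-CRT features (roughly 0.74-0.85
  across cohort seeds at these defaults) is *higher* than real cohorts
  of this kind achieve; the generator optimizes recoverability of its
  ground truth, not effect-size realism.

What passing tests on these cohorts do **not** show: performance on
real patients, robustness to informative missingness, to assay batch
effects, or to the much weaker and collinear effects real hematology
exhibits. One structural divergence is worth stating plainly: because
early counts inherit baseline variance, conditioning response on early
counts makes pre-CRT counts weakly informative too, so pre-CRT-only
models on these cohorts sit above chance -- unlike the near-random
pre-CRT models the clinical report describes. Planting effects on the
within-patient *change* instead would remove this, but at the cost of
diluting the early-count signal below recoverability for
high-dispersion features such as eosinophils; the simpler construction
was kept and the divergence documented.

## Reproducibility and problem sizes

Every stochastic step takes a seed; a single master seed fans out to
per-stage and per-repeat seeds by a counter-based derivation, so any
repeat can be reproduced in isolation and `run_pipeline()` reruns are
byte-identical. The package's own test and example workloads use
desk-scale sizes chosen to exercise the full workflow end to end:
cohorts of 272 (the emulated study size, with 2000--5000-patient
cohorts for distributional checks), 100-repeat benchmarks with ridge
and logistic regression, and 20 master seeds for the recovery study;
the full-study profile (1000 repeats, six model kinds) is a
configuration flag away.

## Known limitations

* The derivation restricts importance to linear-coefficient models;
  tree/network importances are out of scope (the best model in the
  motivating analysis is ridge regression).
* The hyperparameter grids replace an unavailable supplementary
  specification and are intentionally small.
* KS/MLM distances treat coded categorical features as numeric.
* The published-score units (counts in cells/uL, platelets in
  10^3/uL, distance in cm) are assumed from dimensional consistency
  with the printed quartile thresholds; `cohort_schema()` records the
  unit of every column.
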