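---
title: "Methods: two-stage ordinal prediction of knee osteoarthritis severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage ordinal prediction of knee osteoarthritis severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The prediction problem

Knee osteoarthritis (KOA) progresses slowly and irreversibly; by the time it
is radiographically severe the only durable treatment is total knee
replacement (TKR). `kneecast` implements a prognostic pipeline for
radiographically healthy knees: given twelve baseline predictors measured at a
single visit — age, height, weight, baseline Kellgren–Lawrence (KL) grade, and
eight knee-morphology measures read off an anteroposterior radiograph (medial
and lateral joint space, femur width, intercondylar distance, femur–tibia
angle, varus–valgus angle, proximal and distal tibia width) — predict the
knee's *maximal* KL grade over an eight-year follow-up, re-categorised into
three ordered severity classes:

* **KL01** — maximal follow-up KL grade 0–1, healthy;
* **KL2** — maximal grade exactly 2, moderate KOA;
* **KL34** — maximal grade 3–4 *or* TKR during follow-up, severe KOA.

The class distribution is heavily imbalanced (roughly 78% / 11% / 11%), knees
are nested two-per-subject, and the outcome is ordinal. These three facts
drive every design choice below.

# The two-stage cascade

A single three-class classifier must trade the large healthy class against
two small progressed classes. The cascade instead exploits the KL ordering to
decompose the task into two binary problems:

1. **Stage 1** is trained on *all* knees with labels collapsed to
   KL01 vs PROGRESSED (= KL2 ∪ KL34).
2. **Stage 2** is trained *only* on progressed knees, labels KL2 vs KL34.

At prediction time stage 1 decides first; a KL01 verdict is final and stage 2
is never consulted for that knee. Knees predicted as progressed are passed to
stage 2, whose binary output is the final label. Consequently every knee gets
exactly one label, and KL01 can only be produced by stage 1.

Stage 2 is trained on ground-truth progressed rows rather than on rows stage 1
*predicts* as progressed. The training flow is therefore independent of
stage-1 quality, reproducible, and unbiased by stage-1 errors; this is the
cleaner of the two readings of a cascade training diagram and we state it
explicitly because the alternative (training stage 2 on stage-1 survivors) is
also defensible.

## The balanced base learner

Each stage is a bagged ensemble of classification trees in which **every tree
is grown on a class-balanced bootstrap**: if the rarer class has `n_min`
training rows, each tree's sample is `n_min` draws *with replacement* from
every class. This is the defining behaviour of a balanced random forest and
protects minority-class recall, at the price of higher variance per tree
(averaged away by the ensemble). There are several published balanced-forest
variants (undersample-then-bootstrap, per-class bootstrap); we use the
per-class bootstrap because it is the simplest scheme that satisfies the
balance contract, and the fitted object's `sample_log` records the per-tree
class counts so the contract is assertable after every fit.

The bootstrap indices are drawn by `balanced_bootstrap()`; tree growing on
exactly those samples is delegated to `ranger` (per-split feature subsampling
of ⌊√p⌋ candidates, Gini impurity, unlimited depth, terminal nodes down to a
single observation). Predictions average per-tree leaf class probabilities;
`vote = "hard"` switches to per-tree majority votes. Exact probability ties
resolve to the earliest label in the fixed class order, which makes
prediction deterministic. The default of 3000 trees per stage follows the
tuned setting of the study the pipeline reproduces (beyond 3000 trees,
performance no longer improved); the test suite and the examples use far
fewer trees because the tasks there are smaller.

# Cohort construction

`apply_exclusions()` encodes the eligibility pipeline for a working-age,
initially healthy population. Rules fire in a fixed, documented order and each
removal is attributed to the first rule that applies, which makes the
exclusion report deterministic and auditable:

1. subjects with baseline KL ≥ 2 in either knee (prevalent OA);
2. subjects outside the closed age window [45, 67];
3. subjects with prior knee injury or surgery (secondary OA);
4. subjects whose follow-up weight ever differs from baseline by more than
   10 kg (strict inequality — baseline weight is a predictor and large drift
   would decouple it from the outcome);
5. knees without an eight-year KL observation, **unless** a follow-up KL ≥ 3
   (or TKR) was already observed: since KOA does not reverse, such knees are
   certain to be severe at eight years and are retained ("rescued");
6. knees with missing morphology (no usable radiograph);
7. knees with no follow-up KL information at all and no TKR (unlabelable).

Rules 1–4 act on whole subjects; the rescue in rule 5 is knee-level, so a
subject can contribute a single knee. A TKR with no recorded follow-up grades
is labeled KL34 — replacement is itself the severe endpoint — an assumption we
state because follow-up conventions differ between registries.

`recategorize_target()` takes the maximum over *observed* follow-up grades
(missing visits are skipped, never imputed) and is monotone: raising any
follow-up grade can never lower the severity class.

# Evaluation protocol

`make_fold_plan()` + `run_cv()` implement subject-grouped stratified k-fold
cross-validation repeated r times (defaults k = 10, r = 25). Subjects — never
knees — are assigned to folds, so bilateral knees always share a fold and no
subject's data can leak between train and test; this is asserted in every
cell. Stratification uses a subject-level label, the subject's
maximum-severity knee: the simplest rule that simultaneously satisfies
"folds reflect the class distribution" and "subjects stay whole". Within each
stratum subjects are shuffled and dealt round-robin into folds through one
shared sequence, which keeps fold sizes globally equal while spreading every
stratum across folds.

Per-cell performance is stored as the 3×3 confusion matrix — the single
source of truth — from which two imbalance-aware metrics are derived:

* **balanced accuracy (BA)**: the unweighted mean of per-class recalls
  (classes with zero support in a fold are excluded from the mean);
* **weighted F1 (WF1)**: per-class F1 averaged with weights equal to
  true-class supports (a class with zero support gets weight zero; a class
  with zero precision + recall gets F1 = 0).

Summaries report mean ± SD across all k·r cells and, separately, across
repeat means; the two coincide in expectation for equal-size folds but the
SDs differ, so both are exposed.

## Comparing two models

Fold-level CV scores are not independent — training sets overlap heavily —
so a naive paired t-test is anticonservative. `corrected_cv_ttest()`
implements the corrected repeated k-fold CV test: with per-cell differences
$x_{ij} = a_{ij} - b_{ij}$,

$$t = \frac{\tfrac{1}{kr}\sum_{ij} x_{ij}}
        {\sqrt{\left(\tfrac{1}{kr} + \tfrac{n_2}{n_1}\right)\hat\sigma^2}},
  \qquad
  \hat\sigma^2 = \tfrac{1}{kr-1}\sum_{ij}(x_{ij} - m)^2,
  \qquad df = kr - 1,$$

two-tailed, with significance declared at α = 0.01. Here $m$ is the plain
mean of the differences $\tfrac{1}{kr}\sum x_{ij}$ — the centring in
$\hat\sigma^2$ is only meaningful about the true mean, and we treat the
occasionally-printed $\tfrac{1}{kr-1}$ normaliser for $m$ as a typographical
slip. $n_2/n_1$ is the test/train instance ratio; fold sizes vary by a knee
or two, so the nominal ratio $1/(k-1)$ is the default and the exact observed
ratio is an option. Both models must come from the *same* fold plan; the
pairing is checked and refused otherwise. Degenerate cases are defined
explicitly: all-zero differences give t = 0, p = 1; identical nonzero
differences give an infinite statistic with p = 0 and a warning.

# The synthetic cohort generator

The study population itself is access-restricted, so the package ships a
seeded generator whose output emulates the published summary statistics and
makes the whole pipeline testable end to end.

**Predictors.** Marginals are truncated normals around the published
means/SDs (age 56.7 ± 6.1 y, weight 76.2 ± 15.7 kg, medial joint space
4.7 ± 0.9 mm, …), truncated at physiologic bounds (positive lengths, age
clipped to the eligibility window). Where truncation is material (age), the
underlying location is moment-corrected by root-finding so the *truncated*
mean equals the published one. Baseline KL is Bernoulli on {0, 1} with mean
0.18: eligibility requires baseline KL < 2, and no {0, 1} variable with that
mean can reach the published SD of 0.57, so only the mean is matched. The
published height of "165.1 ± 20.0 mm" is used verbatim with the unit treated
as a label. Distinct predictors are independent by default — the published
table gives marginals only, and the between-predictor correlation matrix is
deliberately out of scope — while left/right morphology within a subject
shares a configurable correlation (default 0.6: bilateral knee geometry is
strongly but not perfectly concordant).

**Outcome.** A proportional-odds latent model: a latent progression score,
linear in the standardized predictors plus Gaussian heterogeneity
(`noise_sd`, default 0.25), pushed through an ordinal logistic link with two
cut-points. The cut-points are calibrated by root-finding on the realized
scores of the cohort being generated, so the marginal class prevalence hits
the configured 77.7/11.5/10.8% at *any* loading strength. Follow-up KL
trajectories are then built monotone non-decreasing from the baseline grade
to a class-consistent maximum, with grade-step times drawn uniformly over the
five visits; TKR flags occur only in KL34 knees; follow-up weights stay
within ±10 kg of baseline so a default cohort is fully eligible.

**Effect directions and magnitudes.** Default loadings are positive for
weight, age and baseline KL and negative for the varus–valgus angle (varus
alignment worsens prognosis), with smaller negative/positive loadings on
lateral joint space and distal tibia width — the direction profile reported
by the predictor-importance (SHAP) analysis of the study. Magnitudes
concentrate on weight and baseline KL, mirroring the reported importance
ordering, and were calibrated *once*, together with `noise_sd`, so that a
default cohort at study size (683 subjects, 79% bilateral ⇒ ≈ 1222 knees)
poses a problem of the reported real-data difficulty: with 200-tree stages we
measured cross-validated WF1 ≈ 0.84 and BA ≈ 0.69 against the published
78.3% / 68.2%. An earlier candidate profile that spread the same total signal
evenly over six predictors was rejected at design time: it made the class
boundaries thin diagonal slabs that axis-aligned trees cannot represent
(CV BA 0.78 at `separation = 10` against a balanced-Bayes ceiling of 0.96),
violating the intended contract that large separation be recoverable.

`simulate_separable_cohort(config, separation)` scales all loadings by
`separation`: 0 gives class-independent predictors (any classifier is at
chance, BA ≈ 1/3), 10 gives near-deterministic boundaries used for
parameter-recovery testing.

**Reproducibility.** One root seed; every subject draws from its own derived
substream, so enlarging a cohort appends subjects without reshuffling earlier
predictor draws. One caveat: because the ordinal cut-points are calibrated on
the realized cohort, class labels of early subjects can shift slightly when
the cohort grows — prevalence exactness was judged more valuable than
label-level prefix stability.

## What the generator does *not* emulate

Passing tests on synthetic cohorts show the pipeline is correct, not that the
real-data performance numbers transfer. The generator omits, deliberately:
between-predictor correlations (e.g. femur width and tibia width are surely
correlated in vivo); any nonlinearity or interaction in the risk surface (the
latent model is linear); drift in morphology over follow-up; and measurement
error of the radiograph readings. Real cohorts are harder in some of these
directions and easier in others; conclusions about the real population
require the real data.

# Numerical and protocol choices

* Problem sizes: module tests run on cohorts of 150–500 subjects with 15–50
  tree ensembles; the end-to-end recovery check uses 1000 subjects
  (2000 knees), k = 10, r = 2 and 200-tree stages; the null-calibration check
  uses 100 cohorts of 80 subjects with k = 5, r = 3 and 25-tree stages. These
  sizes give stable assertions while keeping a full run of the suite in the
  low minutes.
* All RNG flows from explicit seeds through named substreams (simulation,
  fold plan, per-cell stage forests), so every reported number is exactly
  reproducible; `ranger` is pinned to one thread during fitting and
  prediction, since multi-threaded prediction reorders floating-point
  reductions.
* Degenerate CV cells (a training split missing a stage-2 class) are
  recorded as failures and skipped, never silently imputed; model comparison
  refuses result pairs with failed cells.
* A knee with TKR but no follow-up grades is severe by definition; a knee
  with neither is an error, not a silent drop, except inside
  `apply_exclusions()` where it is removed under its own report category.

# Known limitations

* The generator's independence of distinct predictors makes the synthetic
  task intrinsically more axis-aligned than the real one; tree ensembles are
  mildly flattered by this.
* Stratification by the subject's worst knee is one of several defensible
  rules; with very small cohorts and k = 10 some folds may still miss a
  minority class, which surfaces as recorded cell failures rather than as an
  error.
* The cascade is structured for exactly three ordered classes; extending to
  more classes means chaining further binary stages, which the current
  implementation does not do.
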