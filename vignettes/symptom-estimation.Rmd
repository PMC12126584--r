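---
title: "Estimating Parkinson's motor symptoms from wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Parkinson's motor symptoms from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Parkinson's disease produces motor symptoms — tremor (a rhythmic 4–6 Hz
oscillation, rated 0–4 on the MDS-UPDRS ordinal scale), bradykinesia
(pathological slowness) and dyskinesia (involuntary writhing, a medication
side effect) — that fluctuate within a day as medication wears off. A wrist
accelerometer worn during activities of daily living (ADL) records the
superposition of voluntary task motion and these symptoms, so symptom
estimation becomes a multivariate time-series classification problem with
three hard properties: the symptom accelerations ride on top of highly
variable voluntary motion, labels exist only per task performance, and
clinical datasets are small and heavily imbalanced.

`pdmotor` implements a complete, tested pipeline for this problem: a
synthetic cohort generator, window segmentation, grouped stratified
splitting and random search, three classifier families, an evaluation and
calibration toolbox, almost-stochastic-order model comparison, and a
task-level misclassification analysis.

## The synthetic cohort generator

Clinical accelerometer repositories are access-controlled, so the package
ships a generator whose output has the statistical structure the analysis
pipeline assumes. Each recording is a 3 × T series at 50 Hz built
additively:

* **gravity** — a constant 9.81 m/s² offset along a random, per-recording
  fixed orientation (raw wrist data are not gravity-compensated);
* **voluntary motion** — band-limited Gaussian noise in a task-specific
  frequency band and intensity (e.g. walking ≈ 0.8–3.5 Hz at 2.4 m/s²,
  sitting ≈ 0.1–1 Hz at 0.15 m/s²), with a random per-recording axis
  loading;
* **tremor** — a sinusoid with frequency drawn uniformly in 4–6 Hz, random
  phase and axis, amplitude `tremor_amp × severity` (default 0.6 m/s² per
  severity unit);
* **dyskinesia** — band-limited noise in 1–4 Hz (default scale 0.8 m/s²)
  when present;
* **bradykinesia** — a multiplicative attenuation of the voluntary
  component (default 0.55) plus a mild narrowing of its band towards low
  frequencies, so bradykinetic recordings show the lower magnitude standard
  deviation observed clinically.

An additive model is a deliberate simplification: symptoms are superimposed
on ADL accelerations rather than interacting with them, and no biomechanical
coupling is attempted. Recording durations are truncated-normal
(mean 29.2 s, SD 11.6 s, floor 5 s — the floor avoids recordings shorter
than any useful window). Labels are drawn once per patient-and-task, so
repetitions of a task share labels as they do within one clinic visit. The
default prevalence table is heavily imbalanced on purpose (70% tremor-free,
dyskinesia present in ≈11% of recordings, severe tremor below 1%); every
probability is configurable. The task catalog contains 18 ADL profiles whose
bands and intensities are plausible defaults, not calibrated against any
device — per-task spectral truth is unknown, and this is the main feature of
real data the simulator does **not** emulate. Passing recovery tests on
synthetic cohorts therefore demonstrates that the estimators and the
evaluation machinery are correct, not that the classifiers reach any
particular accuracy on clinical data.

Cohorts are a pure function of `(config, seed)`; identical inputs reproduce
bit-identical samples.

## Windowing and label handling

Classifiers need equal-length inputs, so recordings are segmented by a
forward-sliding window (default 30 s with 50% overlap). Indexing is 0-based
and half-open; the step is `round(L × (1 − overlap))` with halves rounded
away from zero; only full windows are emitted, so short recordings simply
contribute nothing. Every window inherits its recording's labels — a known
limitation when symptoms fluctuate within a recording, accepted here as in
the clinical annotation protocol. Because the most severe tremor examples
are rare and short, severities 3 and 4 are merged into one class "3–4"
before training. Recordings with missing or implausible annotations
(tremor outside 0–4, non-boolean presence flags) are dropped with a removal
log.

## Data splitting and hyperparameter search

All splits operate on whole patients, never on windows, so no patient's data
can appear on both sides of any boundary. Stratification targets per-class
totals (window counts or durations): patients are assigned greedily, largest
first, each to the split or fold whose class totals gain least squared
deviation from its target share — a small bin-packing heuristic; k-fold
assignment additionally caps fold sizes at ±1 patient. Randomness only
breaks ties (patient order), so folds are deterministic under a seed and
invariant to input order.

The random-search driver samples the Inception-network space: window length
uniform on [3, 30] s (with replacement), filter length 8–255, depth 1–11 and
filters-per-module in {2, 4, 8, 16, 32, 64} — the latter three without
replacement, refilling an axis's pool when it is exhausted (60 trials exceed
some axis cardinalities; refilling keeps draws uniform while maximizing
coverage). A 60-trial × 5-fold search schedules exactly 300 fits; a dry-run
mode enumerates jobs without fitting, and a failing fit marks its trial
failed without stopping the search. Model selection defaults to average
precision (mAP for tremor).

## The three classifier families

**Random convolutional kernels + ridge.** 10 000 kernels with the
transform's published defaults (lengths {7, 9, 11}, mean-centred normal
weights, bias U[−1, 1], dilation `floor(2^a)` capped so the dilated span
fits the window, padding on/off equiprobably) are convolved against every
channel independently; each intermediate series is pooled to the proportion
of strictly positive values (PPV; ties at exactly 0 count as non-positive)
and the maximum, giving `2 × kernels × channels` features. Windows are
z-normalized per channel before convolution (the transform's convention).
The head is a one-vs-rest least-squares ridge classifier on standardized
features, solved in closed form by SVD, with the regularization strength
picked from 10 log-spaced values in [1e-3, 1e3] by internal 5-fold CV —
grouped by patient when groups are available, stratified otherwise. Class
likelihoods are mapped through a softmax to probabilities. The hot
convolution loop is compiled (C++), as this family's implementations
usually are.

**Inception-style network.** Each module feeds a 1×1 bottleneck (default 32
channels; a strictly univariate bottleneck is available) into three parallel
convolutions of lengths `filter_size`, `filter_size/2`, `filter_size/4`
(minimum 2), concatenated with a max-pool(3)+bottleneck branch, then batch
norm and ReLU; output length always equals input length. The default
network stacks six modules with a projected residual shortcut every third
module (the final module always connected), global average pooling and a
softmax layer; the ensemble averages five networks differing only in
initialization seed. An alternative reading of "number of filters" — as the
number of halving-length single-filter branches — is available via
`branch_mode = "halving_count"`; the standard three-branch architecture is
the default because the default-hyperparameter results depend on it.
Training minimizes categorical cross-entropy with Adam (step size 1e-3 —
an assumption, since only the baseline's optimizer is specified — batch 64,
600 epochs by default with no early stopping; desk-scale runs override the
epoch count). As the network's own input normalization, each window is
centred per channel: this removes the orientation-dependent gravity offset,
which otherwise dominates the input variance, while deliberately preserving
amplitude — the bradykinesia signature. The whole network (im2col
convolutions, batch norm, max-pool, Adam) is implemented in base R with
BLAS matrix products; the backward pass is verified against finite
differences in the test suite.

**Wavelet-feature MLP baseline.** The acceleration magnitude is decomposed
over nine levels of a Daubechies-4 (8-tap) DWT with symmetric boundary
extension (the wavelet family is an assumption; it is configurable), and
seven statistics — RMS, SD, maximum, excess kurtosis, skew, Welch-PSD
maximum and minimum — are computed for the original magnitude and each
detail level: 70 features in a fixed order. Kurtosis and skew of a constant
series are defined as 0 to avoid NaN propagation. Features are computed on
the magnitude because the error analysis consistently works on magnitude
series; a per-axis mode would triple the count and is not the default. The
head is a 70→128→128→K network with sigmoid hidden units and a softmax
output, trained with Adam on standardized features.

## Evaluation, calibration and significance

* **Balanced accuracy** is the mean per-class recall (0.5 = binary chance).
* **Average precision** is the recall-weighted sum of precision over
  descending unique score thresholds with the `R₋₁ = 0` convention and no
  interpolation; mAP averages one-vs-rest APs with equal weights.
* **Macro F1** uses `2PR/(P+R)` per class, defined as 0 when both P and R
  vanish.
* **AUROC** is the rank statistic for binary tasks; multiclass uses
  one-vs-one averaging over unordered class pairs (less sensitive to
  imbalance than one-vs-rest), skipping pairs with an absent class.
* **MAMAE** (ordinal tremor) macro-averages per-class mean absolute errors
  with equal class weights — the textual definition; the variant with a 1/N
  prefactor, as the formula is sometimes printed, is available via
  `printed_form = TRUE`.
* **Smoothed ECE**: outcomes are kernel-regressed on predicted
  probabilities with a reflected Gaussian kernel on [0, 1]; the bandwidth is
  the fixed point `σ = smECE_σ`, found by bisection on [1e-3, 1] (the map is
  monotone) to 1e-4, with 1e-3 acting as a bandwidth floor for degenerate
  inputs. A perfectly calibrated predictor scores near 0; a maximally
  anti-calibrated one scores near (slightly below) 1 because the reported
  value equals the fixed-point bandwidth's smoothed deviation, which the
  kernel width itself caps — at 1000 one-sided predictions it lands around
  0.87.

Model comparison uses **almost stochastic order**: the dominance-violation
ratio is the share of the squared quantile-function gap (1000-point uniform
grid) on which the candidate's quantiles fall below the competitor's; the
two directions sum to one. A 1000-iteration bootstrap (resampling both
sides, preserving the 10-vs-10 group sizes) gives a normal-approximation
upper confidence bound `ε̂ + sd(ε*) z₁₋α`, clamped to [0, 1]; dominance is
declared below 0.2 at α = 0.05. Identical degenerate samples report ε = 0.5
and never dominate. **Bootstrap power** resamples both score sets 5000
times and counts one-sided Welch t-tests significant at α — the inner test
is a design choice (running ASO inside every resample would multiply the
cost a thousandfold; for location differences between small score samples
the t-test is the conventional power proxy). Bonferroni correction is
`α/m`; the reference protocol uses m = 31.

## Task-level misclassification analysis

Observed counts `O[task, predicted, true]` are pooled across training
repetitions; expected counts redistribute each `(predicted, true)` total
over tasks proportionally to the task's share of samples at that true class,
so task sums are conserved exactly. A cell is flagged when the two counts
differ by at least 40% — read as a ratio `max(O,E)/min(O,E) ≥ 1.4` in either
direction, since reported pairs like 216/100 are ratio-like — and both
counts are at least 10. Tremor is binarized (severity ≥ 1 = present) before
tabulation. Signal explanations use the magnitude series: Welch PSD (Hann
window, 256-sample segments, 50% overlap — common defaults), trapezoidal
4–6 Hz band power, the magnitude SD, and sample entropy (m = 2,
r = 0.2·SD, Chebyshev distance, self-matches excluded — the standard
physiological-signal convention), with a constant series defined as entropy
0 and a matchless series reported as +Inf with a warning.

## Numerical choices and degenerate inputs

* Ridge: feature SDs below 1e-8 are treated as 1 (constant columns);
  predictions break argmax ties towards the first class.
* Batch norm uses ε = 1e-5 and momentum 0.9 running statistics;
  evaluation-mode forward passes use the running estimates.
* Non-finite training losses abort with diagnostics rather than continuing.
* The DWT recurses while at least 2 coefficients remain, reflecting the
  boundary as needed, so all 9 levels exist for 30 s windows at 50 Hz.
* Welch segments shrink to the series length when it is shorter than 256
  samples; detail-level PSDs use the level's decimated sampling rate.

## Problem sizes in the test suite

The test and acceptance suites exercise the full pipeline at desk scale,
the package's chosen trade-off between coverage and turnaround: cohorts of
6–12 patients over 1–4 tasks with 6–15 s recordings, 5 s (or shorter)
windows, 100–500 random kernels, Inception networks of depth 1–2 with 2–8
filters trained for 5–25 epochs, and MLPs up to 150 epochs. Structural
contracts (10 000 kernels, 300 scheduled fits, 70 features, 128-unit hidden
layers) are always verified at the reference sizes, since they are cheap.
Recovery thresholds (e.g. tremor-presence balanced accuracy ≥ 0.9 on the
easy cohort) were chosen for cohorts whose effect scales make the symptom
clearly learnable; they probe correctness of the chain, not clinical
performance.

## Known limitations

* The simulator's task profiles are not calibrated to any real device or
  cohort; absolute scores on synthetic data do not transfer.
* Single-label windows ignore within-recording symptom fluctuation
  (multiple-instance learning is explicitly out of scope).
* The Inception implementation is CPU-bound base R; it is sized for
  correctness testing and small studies, not for full-scale searches
  (a full 60 × 5 × 3-symptom search at 600 epochs is expressed by the
  driver but impractical without compiled training).
* Medication dynamics, freezing of gait and gyroscope channels are not
  modelled.
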