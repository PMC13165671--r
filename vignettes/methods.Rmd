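---
title: "Methods: self-explaining networks for plantar-force gait screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-explaining networks for plantar-force gait screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by **senngait**, the synthetic
data generator it ships with, and the numerical choices made where the
method description leaves freedom. It is written for a reader who wants to
audit or extend the implementation, not only run it.

## 1. Problem and data representation

The task is binary screening — Parkinson's disease (PD) versus healthy
control (HC) — from vertical ground-reaction-force (GRF) recordings. A
recording is a `T x 16` matrix sampled at 100 Hz: channels 1–8 are plantar
sensors under the left foot, 9–16 under the right, each foot laid out as
(heel, midfoot, midfoot, forefoot, forefoot, forefoot, toe, toe). Labels are
per subject.

Preprocessing is deliberately minimal and leakage-guarded:

1. **Subject-stratified split** (`stratified_subject_split()`): subjects of
   each class are allocated 70/15/15 to train/validation/test by
   largest-remainder rounding, then assigned under a seed. All downstream
   windows inherit the subject's partition; `assert_disjoint_subjects()`
   aborts if any subject appears in two partitions.
2. **Train-only standardisation** (`fit_channel_scaler()`): per-channel mean
   and population standard deviation are computed on the concatenated
   training frames only and then frozen; validation and test recordings are
   z-scored with the training statistics.
3. **Windowing** (`segment_windows()`): fixed 128-timestep windows with
   stride 64 (50% overlap), count `floor((T - 128) / 64) + 1`; trailing
   partial windows are discarded.
4. **Augmentation** (`build_training_set()`), training partition only, two
   augmented copies per window, each passing three stages in sequence:
   Gaussian jitter (sd 0.02 in z-score units), random channel dropout (1–2
   channels zeroed), and same-class CutMix (a contiguous 16–64-timestep
   segment replaced by the same interval of a same-class donor window). A
   class-mismatched donor is a hard error, not a silent skip.

## 2. Architecture

The model is a self-explaining neural network (SENN): its prediction is
*structurally* a sum of concept contributions, so the explanation is the
computation rather than a post-hoc approximation.

**Backbone.** Four residual 1-D convolution blocks with filter counts
(32, 64, 128, 128). Each block is Conv–BatchNorm–ReLU–SpatialDropout(0.15)–
Conv–BatchNorm, added to a skip path (a 1x1 convolution where channel
counts change) and passed through a final ReLU. Max-pooling of width 2
after blocks 1–3 reduces 128 timesteps to 16; global average pooling and
dropout (0.22) yield a 128-dimensional feature `x_gap`.

**Stochastic depth.** During training, block `i` is dropped (replaced by
its skip path) with probability `p_i = ((i - 1) / (L - 1)) * p_L`, `L = 4`,
`p_L = 0.15`, i.e. rates (0, 5%, 10%, 15%). One Bernoulli draw per block per
batch; a dropped block's batch-norm statistics are not updated. With
`p_L = 0` the draw is short-circuited entirely, which makes the
`disable_stochastic_depth` ablation bit-equivalent to setting `p_L = 0`.

**Concept encoder.** `h = tanh(W_h x_gap + b_h)` gives `K = 16` bounded
concept activations, then layer normalisation (with affine parameters)
across the concept dimension yields `h_tilde`.

**Relevance network.** A 128→64→32→16 MLP with ReLU and dropout 0.45,
followed by layer normalisation, yields input-dependent relevance scores
`theta`.

**Aggregation and head.** The scalar aggregate is
`z = sum_k h_tilde_k * theta_k`. The classification head consumes this
scalar only — Dense(16)+ReLU+dropout, then a sigmoid unit — so the
per-window contribution vector `(h_tilde_k * theta_k)_k` sums exactly to
the quantity the head sees. `concept_report()` re-verifies this identity at
analysis time and aborts on violation.

## 3. Losses

The training objective is a sum of five terms (`total_loss()` reports the
decomposition):

* **Label-smoothed BCE**: targets `y_s = y(1 - 0.05) + 0.025`,
  probabilities clipped to `[1e-7, 1 - 1e-7]`, weighted by balanced class
  weights `w_c = N / (C N_c)` (weights are normalised, so their scale is
  irrelevant).
* **Diversity** (`lambda_div = 1e-3`): with `G = H'H` on the
  post-layer-norm concept matrix,
  `|| G / (||G||_F + 1e-12) - I_K ||_F^2`. Because the Gram matrix is
  normalised to unit Frobenius norm, the penalty cannot be driven to zero;
  over equal-norm orthogonal concept designs it attains its minimum
  `(sqrt(K) - 1)^2` — a property the test suite checks in closed form.
* **Sparsity** (`lambda_spar = 2e-4`): mean L1 norm of the relevance rows.
* **Stability** (`lambda_stab = 5e-4`): mean over concepts of the
  population variance of `theta_k` across the batch.
* **Convolutional L2** (`3e-4`): on convolution kernels, included in the
  loss and its gradient. This is distinct from the optimiser's *decoupled*
  AdamW weight decay (`2e-4`), which is applied only to weight matrices and
  kernels (never biases or normalisation affines) at update time.

## 4. Optimisation

AdamW (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) with batch size 64.
The learning rate ramps linearly from 0 to `5e-4` over 5 warm-up epochs and
then follows a cosine to `1e-6` at epoch 120. Early stopping monitors the
window-level validation AUC smoothed by a 3-epoch rolling mean (partial
means while the window fills); improvement must exceed the best smoothed
value by more than `1e-6`, patience is 12 epochs, and the parameters of the
best smoothed epoch are restored. Multi-seed experiments use seeds
(42, 123, 256, 789, 2024) and report `mean ± t_{0.975, n-1} * s / sqrt(n)`
(critical value 2.776 for five seeds).

All forward/backward computation is hand-written R on BLAS matrix
primitives: convolutions are evaluated as a single GEMM on a gathered
im2col buffer (cached in the forward pass and reused for the weight and
input gradients; the input gradient is the convolution with the
time-flipped, transposed kernel). Gradients of every layer — including the
normalised-Gram diversity term — are derived analytically and validated
against central finite differences in the test suite.

## 5. Calibration, thresholding and metrics

* **Temperature scaling** (`fit_temperature()`): minimise validation NLL of
  `sigmoid(logit(p) / T)` over `T in [0.25, 10]` (log-spaced grid, then
  local refinement). If the fitted temperature does not improve the
  fitting-set NLL, `T = 1` is kept, so scaling can never hurt NLL on the
  fitting set. Scaling is strictly monotone and therefore leaves ROC-AUC of
  the scaled windows unchanged.
* **Subject pooling**: a subject's probability is the mean of their
  calibrated window probabilities.
* **Threshold** (`select_threshold()`): `tau*` maximises macro-averaged F1
  on the validation subjects over the grid `{0.01, ..., 0.99}`; ties are
  broken toward the **largest** threshold (favouring specificity in a
  screening context), and classification uses `p >= tau`. On well-separated
  cohorts this tie-break intentionally selects the top of the optimal
  plateau; thresholded point metrics are then conservative for the PD class
  even when AUC is 1, which is visible in the synthetic examples below.
* **Metrics**: confusion-derived rates with zero-denominator ratios
  reported as 0; ROC-AUC by the midrank Mann–Whitney statistic; average
  precision as the step-wise precision–recall integral over tie-grouped
  thresholds; Brier score; expected calibration error with 10 equal-width
  bins.

## 6. Concept analytics

Per window, concept `k` contributes `c_k = h_tilde_k * theta_k`.
`discriminative_stats()` reports, per concept, the absolute class gap
`delta = |mean_PD - mean_HC|` and the signed Cohen's d with pooled
`(n-1)`-weighted standard deviation (zero pooled spread yields a flagged
signed infinity). `concept_sensor_correlation()` correlates concept
activations with the per-window mean raw signal of the eight anatomical
sensor groups (left/right x heel, midfoot, forefoot, toe), which is how a
learned concept is tied to an anatomical hypothesis.

## 7. The synthetic cohort generator

Real insole datasets cannot be redistributed with a package, so the
experiments run on a synthetic generator (`generate_cohort()`) that plants
the clinically documented class differences it is meant to recover:

* Strides are quasi-periodic: intervals are drawn i.i.d. from a truncated
  normal with class-dependent mean (0.95 s PD, 1.05 s HC) and
  coefficient of variation (0.08 PD, 0.03 HC — elevated stride-to-stride
  variability in PD). Stance occupies 62% of the stride; the right foot is
  phase-shifted half a period.
* Within stance, each anatomical region contributes a half-sine force bump
  over its canonical window (heel 0–30%, midfoot 20–60%, forefoot 40–85%,
  toe 60–100% of stance) with region amplitudes (1.0, 0.6, 0.9, 0.8) and
  fixed within-region channel gains.
* PD recordings additionally carry: a 35% **push-off reduction** on
  forefoot/toe amplitudes, a 30% **midfoot window prolongation**, and a 15%
  bilateral **amplitude asymmetry** (left scaled by `1 + a/2`, right by
  `1 - a/2`).
* Between-subject variation is log-normal (scale 0.10 on amplitudes, half
  that on period); sensor noise is additive Gaussian (sd 0.05).

Limits worth stating: the generator produces vertical force only, has no
swing-phase dynamics, no fatigue or turning segments, and its class effects
are stationary within a recording. It is a *recovery benchmark* — the
question it answers is whether the pipeline finds effects known to be
there — not a simulator of clinical gait. Consequently the synthetic task
is much easier than real-cohort screening, and metrics obtained on it
should never be quoted as clinical performance.

## 8. Numerical and scale choices

Choices the method description leaves open, fixed here as package policy:

* **Convolution kernel width 5** ('same' padding, odd width required).
* **Batch-norm** over the time-and-batch axes per channel, `eps = 1e-3`,
  running-statistic momentum 0.1; **layer-norm** `eps = 1e-5`.
* **Initialisation**: He-normal for convolution kernels, Glorot-uniform
  for dense layers, unit normalisation scales.
* **Head width 16** for the scalar-aggregate head.
* **Reduced problem sizes** in examples and tests: the default cohort
  structure (28 PD / 12 HC) is kept, but recording durations of 10–15 s and
  epoch budgets of 3–10 are used so that a full experiment is a
  minutes-scale computation in plain R. These are package-level scale
  choices; every quality threshold checked at these scales (subject AUC,
  concept effect sizes, calibration behaviour) is checked unchanged, not
  relaxed.
* The test suite pins behavioural contracts: analytic gradient checks
  against central finite differences, closed-form penalty values,
  scripted early-stopping traces, metric hand-oracles, an external ROC-AUC
  cross-check, and bit-level reproducibility of a full run under a fixed
  seed.

## 9. Reproducing an experiment

```r
library(senngait)

cohort_cfg <- cohort_config(duration_s = 15, seed = 1)
config <- experiment_config(
  cohort = cohort_cfg,
  optimizer = optimizer_spec(t_max = 10, warmup = 3))

run <- run_experiment(config, seed = 42, verbose = TRUE)
run$metrics                 # subject-level test metrics at tau*
tidy(run$concepts)          # per-concept class gaps and effect sizes
autoplot(run)               # reliability diagram
write_run_bundle(run, "run42")
```

Multi-seed summaries follow with `run_multi_seed()`, and every ablation of
the loss terms, stochastic depth or temperature scaling is one
`experiment_config(ablate = ...)` switch away.
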