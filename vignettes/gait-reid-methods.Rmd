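---
title: "Methods: inertial gait re-identification with gaitreid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inertial gait re-identification with gaitreid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`gaitreid` is a closed-set person re-identification pipeline for chest-worn
6-channel IMU recordings of walking: synthetic signal generation, fixed-grid
step/stride segmentation, robust scaling, a bidirectional GRU classifier
with a time-distributed softmax head, and CMC/rank-k/mAP evaluation. This
vignette explains the models and conventions, the parameters that matter,
what the synthetic generator does and does not emulate, and the design
choices made where the design was genuinely open.

# The synthetic gait world

## Signal model

Real chest-IMU walking data is quasi-periodic at the stepping frequency
*f* ∈ [1, 2] Hz. The simulator replaces biomechanics with the minimal
spectral structure that makes the downstream task meaningful. Per channel
*c* (3 accelerations in m/s², 3 angular velocities in rad/s):

s_c(t) = b_c + Σ_{k=1..K} A_{c,k} cos(2π k f t + φ_{c,k})
       + α A_{c,1} cos(π f t) + ε_c(t),  ε_c(t) ~ N(0, σ_c²)

* **Harmonics (K = 4).** A subject's identity is carried by the joint draw
  of f (uniform on [1, 2] Hz), the 6 × K amplitude matrix and the phase
  matrix; two subjects coincide with probability 0. Amplitudes decay with
  harmonic order; dominant amplitudes are drawn at scale 2 m/s² (acc) and
  0.8 rad/s (gyro), roughly the magnitude of chest-level oscillation in
  walking.
* **Asymmetry term (α ∈ [0.05, 0.35) by default).** The half-frequency
  component cos(π f t) has period 2/f — one *stride* — so the two steps of a
  stride are distinguishable and stride windows carry information step
  windows cannot. With α = 0 the signal is step-periodic (period 1/f); with
  α > 0 it is exactly stride-periodic. Both facts are asserted by property
  tests.
* **Noise floor.** σ_c = 5% of the channel's dominant amplitude. This keeps
  single-window identification nontrivial (posteriors are not degenerate at
  epoch 1) yet achievable at desk scale.
* **Gravity.** The baseline puts +9.81 m/s² on `acc_z`, mirroring a raw MEMS
  accelerometer in the chest-mounted sensor frame. Scaling removes it; it
  exists so the robust scaler has something realistic to remove.

## Cohort model

`make_cohort()` draws gender by a fixed male fraction (default 49/86),
acquisition setup by fixed counts (default proportional to 40:20:26 over
setups A/B/C), and age from a truncated normal on [17, 72] years.

**Age calibration.** The target moments (mean 33.8, SD 14.8) cannot be
attained by truncating N(33.8, 14.8²) — the left truncation point sits only
1.1 SD below the mean, and the truncated mean rises to ≈ 37.1. The generator
therefore calibrates the *underlying* (μ, σ) by a deterministic Nelder–Mead
moment fit before sampling via the inverse CDF. The target is still not
exactly reachable on [17, 72] (the attainable optimum is ≈ mean 34.3 / SD
13.6); the cohort-statistics test asserts the documented tolerance
(mean within 33.8 ± 1.0, SD within 14.8 ± 2.0 over 1000 cohorts) rather than
a false exactness. Alternatively, `age_group_counts` pins exact decade-bin
counts (ages uniform within the bin) — the hybrid-cohort fixture uses counts
3/48/9/10/9/7 over G1–G6, which reproduces both the bin structure and,
incidentally, moments close to the targets.

**Age groups.** G1 = 10–19 y through G6 = 60–79 y, bounds inclusive. (G6 is
60–79, not 60–69: the cohort's age range extends to 72, and a 60–69 bin
would leave subjects unassignable.)

## Perturbations

`inject_perturbation()` emulates two acquisition variations:

* `surface` — per-channel amplitude rescale about the channel mean by a
  factor 1 + m·U(0.5, 1) plus additive noise with SD = m × channel SD. Both
  effects strictly increase per-channel variance, which the tests assert.
* `faked-gait` — a subject deliberately changing their walk: one global
  tempo factor 1 ± m·U(0.5, 1) plus per-2-second-segment phase jitter,
  applied by linear-interpolation resampling along a warped time axis.
  Output length equals input length; the dominant autocorrelation lag
  moves, which is the testable signature of a forged cadence.

`magnitude = 0` returns the input unchanged, exactly.

## What a green test does not establish

The generator is a stated world: sums of sinusoids with stationary noise.
Real gait has stochastic cycle-to-cycle variability, transient events
(turns, stops), sensor drift, posture-dependent gravity projection, and
inter-subject similarity structure that sinusoidal signatures do not
capture. Identity-recovery results on synthetic cohorts therefore validate
the *pipeline* (shapes, scaling, training dynamics, ranking arithmetic) —
they do not estimate real-world re-identification accuracy, and the
published accuracy tables from the motivating study are deliberately not
reproduced (its recordings are not publicly deposited).

# Segmentation

At 75 Hz and a 1–2 Hz stepping frequency, 100 samples bracket one step and
200 samples one stride, so windows are fixed-length (100/200) and cut
blindly on a grid at start frames 0, hop, 2·hop, … (0-based, half-open
ranges), dropping a trailing partial window. There is no heel-strike
detection — by design the method is frequency-based, not event-based.
Defaults are non-overlapping (hop = window length); with
hop_step = hop_stride / 2 and stream lengths multiples of 200, the corpus
satisfies steps = 2 × strides exactly. Note the published corpus totals
(1,134,000 frames; 19,614 steps; 9807 strides) are mutually inconsistent
under any single hop policy; `window_census()` exposes both hops and the
tests reproduce each total under its own construction.

# Robust scaling

Per channel, x → (x − median) / IQR with statistics pooled over **all frames
of all training windows** (a global scaler, fit once before training — test
windows never touch it). Conventions that had to be fixed:

* quantile type 7 (linear interpolation between order statistics), the R
  default, asserted by a hand-computed fixture;
* zero IQR (degenerate constant channel) replaced by ε = 1e−9, so degenerate
  synthetic channels scale to 0 rather than dividing by zero;
* no smoothing, filtering or gravity removal — the network trains on raw
  scaled signals.

Per-recording scaling (fitting one scaler per stream) was considered and not
exposed as a flag: with a single chest-worn sensor per recording the global
fit matches the deployment model of one enrolled scaler per system, and a
per-stream variant would leak recording identity into the normalization.

# The recurrent model

## Cell

The exported `gru_cell_step()` is the reference implementation of the gate
equations (reset r_t, update z_t, candidate h̃_t, convex update
h_t = z_t ⊙ h_{t−1} + (1 − z_t) ⊙ h̃_t) and returns the full gate trace.
Properties asserted: gates in (0,1), candidate in (−1,1), h_t componentwise
between h_{t−1} and h̃_t, rollouts from h_0 = 0 bounded by 1, and
equivalence with an independent scalar-loop oracle to 1e−12.

## Network

`train_classifier()` trains a stack (default 2) of bidirectional layers:
each layer runs its forward cell over t = 1…T and its backward cell over the
reversed sequence and concatenates per timestep (n units → 2n features). A
time-distributed dense softmax head emits one distribution over subjects per
timestep; the loss is mean categorical cross-entropy over all timesteps with
the window's subject as target at every timestep, minimised by Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e−8). Implementation notes:

* No autodiff backend is assumed: forward, backpropagation through time and
  Adam are hand-written over base matrix algebra. The batched path is tied
  to the reference cell by `as_gru_stack()` + `bidirectional_forward()`
  equivalence tests.
* Initialization: uniform fan-in scaled U(±1/√fan_in), biases zero, seeded.
  Initial hidden states are zero in both directions.
* Dropout (default 0.5) is inverted dropout applied after each recurrent
  layer, training time only, independent per element and timestep.
* Candidate activation is tanh by default ("relu" selectable; it voids the
  (−1,1) candidate bound and the convexity-derived |h| ≤ 1 rollout bound).
  The softmax is applied only at the output head.
* Determinism: all randomness (init, shuffling, dropout) derives from
  `config$seed` inside an RNG scope that restores the caller's state;
  repeated runs are bit-identical under single-threaded BLAS.

## Aggregation and prediction

A window's score vector is the arithmetic mean of its per-timestep
posteriors (default), preserving the score information CMC ranking needs; a
normalised per-timestep argmax vote is available (`aggregate = "vote"`).
Predicted class is the argmax with ties broken toward the lowest class
index.

# Evaluation

* **Protocols.** Subject-wise half split (odd counts favour training) and
  subject-stratified k-fold (default k = 10); both seeded, both guarantee
  every subject in every training partition — a closed-set requirement.
  Cohort restrictions (gender / age group / setup) are applied *before*
  splitting, so each restricted experiment retrains on the surviving
  subjects only.
* **Ranking.** rank(true) = 1 + #{strictly greater scores} + #{ties at
  lower class index}; deterministic under ties.
* **CMC / rank-k.** matching_rate[k] = fraction of queries with rank ≤ k;
  nondecreasing with terminal value 1; rank-k reported as percentages at
  k ∈ {1, 5, 10, 20}, two decimals.
* **mAP.** With exactly one relevant class per query, average precision is
  1/rank, so mAP = mean reciprocal rank × 100 and mAP ≥ rank-1 always. A
  gallery-instance mAP (other test windows as gallery, ranked by cosine
  similarity of aggregated posteriors, all windows of the query's subject
  relevant) is available as `method = "gallery"` for comparability with
  vision re-identification conventions.
* **Granularity.** Rank-k is per *window*, not per subject — the natural
  granularity of window-level confusion matrices.

Both CMC and mAP are verified against an exhaustive brute-force ranking
oracle on random score matrices, including tie rows.

# Orchestration

One global experiment seed fans out to per-stage seeds via a rolling string
hash (`derive_seed(seed, stage)`), so reconfiguring one stage does not
perturb another's draws; all derived seeds stay below 2³¹. Experiment
configurations are YAML (JSON parses through the same loader) with strict
unknown-key rejection and range validation; defaults reproduce the tuned
operating point (512 units, 2 layers, dropout 0.5, learning rate 0.001,
batch 32, 30 epochs). `hyperparameter_sweep()` varies n_units / dropout /
learning_rate / epochs on a cartesian grid and tabulates rank-1 and mAP per
point.

# Desk-scale fixtures and budgets

The full 512-unit / 30-epoch configuration is CPU-hostile (the original
model trained on a GPU); the package's standard fixture is 10 subjects with
stepping frequencies evenly spaced on [1, 2] Hz, 90 s each at 75 Hz, trained
at 64 units / 10 epochs (`fixture_streams()`, `fixture_model_config()`).
On one CPU this trains in about a minute and reaches rank-1 = 100% held
out for both steps and strides; the test suite's stride-vs-step comparison
runs it over 5 seeds. The 512-unit architecture is exercised for shape
(1024 features per timestep), not trained, in tests.

# Known limitations

* The simulator's separability is optimistic: evenly spaced stepping
  frequencies make the fixture nearly linearly separable, so ceiling
  effects (rank-1 = 100%) are expected and the stride-vs-step comparison is
  correspondingly weak evidence.
* Closed-set only: no open-set rejection of unenrolled walkers.
* No event-based gait-cycle detection or resampling; windows assume the
  nominal 75 Hz rate.
* Training memory scales with batch × window length × units (BPTT caches);
  512-unit training at batch 32 wants ~2 GB and is not exercised by tests.
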