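---
title: "Methods: seated chest-movement recognition and the Navon switch-cost analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seated chest-movement recognition and the Navon switch-cost analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chestmotion` bundles two methodologically distinct pieces: a
sensor-to-label activity-recognition pipeline for subtle seated chest
movements, and the subject-level statistics used to relate those movements
to attentional switching performance and stress. This vignette documents
the models, their assumptions, the tunable parameters, and the design
choices made where the methodology left the design open.

## 1. The signal model and what it emulates

The simulator emulates a smartphone worn flat at the centre of the
clavicle: the device z axis carries gravity (9.81 m/s²) when seated
upright, x is lateral and y anterior–posterior. Each movement class has a
deliberately simple kinematic signature:

| class       | structure                                                        | default |
|-------------|------------------------------------------------------------------|---------|
| `still`     | gravity + white noise only                                       | —       |
| `swing`     | lateral (x) sinusoid                                             | 0.6 Hz, 2.0 m/s² |
| `rock`      | anterior–posterior (y) sinusoid                                  | 0.6 Hz, 2.0 m/s² |
| `rotate`    | quarter-period phase-shifted oscillation on x and y              | 0.5 Hz, 1.5 m/s² |
| `walk`      | vertical bounce at stride frequency + lateral sway at half rate  | 2.0 Hz, 3.0/1.0 m/s² |
| `stand_sit` | alternating-sign vertical Gaussian pulses on top of gravity      | every 2.5 s, 4.0 m/s², σ = 0.3 s |

White noise (sd 0.3 m/s²) represents sensor noise and incidental body
motion. The frequencies sit inside the 2–5 s time span typical of seated
daily movements and safely below the 5 Hz Nyquist limit of the 10 Hz
working rate; `simulate_activity()` refuses any parameterisation at or
above Nyquist. Oscillation phases are random per call, and
`simulate_training_session()` applies multiplicative log-normal jitter
(amplitudes sd 0.15, frequencies sd 0.10 on the log scale) from a
subject-seeded stream, so different subjects genuinely move differently —
without this, leave-one-subject-out validation would be meaningless.

*What the simulator does not emulate:* harmonics and broadband content of
real biomechanics, posture drift, sensor placement variability,
gyroscope channels, or movement co-articulation. Passing tests on this
generator therefore demonstrate that the pipeline and classifier are
correct and can generalise across the simulated inter-subject
variability; they do not certify accuracy figures on real recordings,
whose per-participant accuracies cannot be reproduced without the
original data.

## 2. Preprocessing

The working representation is: resample to 10 Hz (linear interpolation;
upsampling refused) → slice into windows of 20 samples (2 s) advancing by
10 samples (50% overlap; window count `floor((N−20)/10)+1`) → per-window,
per-axis mean subtraction (gravity correction) → one-sided DFT magnitudes
(11 bins of 0.5 Hz × 3 axes). Conventions that needed fixing:

- **Windows** are half-open `[start, start + width)` with 0-based starts.
  A window's label is the majority per-sample label; exact ties take the
  first sample's label (documented, tested).
- **No taper** (rectangular window) before the DFT — only mean
  subtraction precedes the transform. Mean removal makes the DC bin
  vanish, which is the gravity correction.
- **Magnitudes, not phase**: the classifier input is the one-sided
  magnitude spectrum, the conventional representation for activity
  recognition; phase is discarded. A time-domain variant would be
  straightforward (the classifier consumes any `n × T × 3` array) but the
  frequency-domain form is the default and only tested path.
- Parseval's identity (`sum(x²) = (1/N)·Σ|X_k|²` against the two-sided
  spectrum) is enforced in tests at 1e-9 relative, and the pure-tone bin
  placement is checked against a direct DFT-sum oracle.

## 3. The classifier

A deliberately small sequence classifier: input 3 channels × 11 time
steps → LSTM(20) → dropout(0.1) → LSTM(30, last time step) → dense(6) →
softmax, cross-entropy loss, SGD with momentum (lr 0.001, momentum 0.9 —
the solver's conventional default, as only the solver family is
specified), minibatch 30, 300 epochs, no early stopping. The "20 + 30"
stacking with dropout as the middle layer is the most literal reading of
a three-hidden-layer listing (20 / dropout / 30). Sequence classification
uses the final hidden state because each window carries one label.

Implementation choices:

- The forward/backward core is RcppArmadillo; gate order is
  (input, forget, candidate, output), forget biases start at 1, other
  weights are Glorot-uniform. The analytic gradients are verified against
  central finite differences in the test suite (tolerance 1e-5).
- Dropout applies to the inter-layer connection only (not the
  recurrence), as inverted dropout drawn from R's RNG — so a single
  `seed` in `lstm_config()` makes initialisation, shuffling and dropout,
  and therefore the entire training run, bit-reproducible. Inference
  disables dropout and is a pure function of (model, input).
- Spectra are scaled by 1/width before entering the network so a
  unit-amplitude sinusoid contributes an O(1) input; without this the
  raw DFT magnitudes (up to ~20 at these amplitudes) saturate the gates.
- Prediction ties resolve to the lowest class index in the canonical
  order (walk, stand_sit, rotate, swing, rock, still).
- Confusion matrices are oriented rows = predicted, columns = actual.

Leave-one-subject-out CV trains one model per held-out subject with a
fold seed derived deterministically from the config seed. On the default
synthetic cohort (5 subjects, 60 s per activity — 359 windows each) the
mean LOSO accuracy is far above the 0.70 property threshold asserted in
the acceptance tests, and a label-permuted control collapses to chance
(1/6 ± 0.1), which is the package's guard against information leakage
through the pipeline. With the default minibatch of 30, small fixture
data sets see few parameter updates per epoch; tests on tiny fixtures
therefore use a larger learning rate (0.01) rather than more epochs.

## 4. Navon statistics

**Shift tagging.** In the 40-trial mixed phase, trial *i* (*i* ≥ 2) is a
*shift* trial iff its target level differs from trial *i−1*; the first
trial has no predecessor and is tagged `undefined` and excluded. This
exclusion is the only reading under which the mixed phase can be half
shift and half nonshift after conditioning on transitions. Condition
means use accurate trials only (for all four conditions — the accuracy
criterion is stated for shift trials and applied uniformly); shift
accuracy is correct shift trials over shift trials.

**RM-ANOVA.** One-way within-subject decomposition on the complete
`n × k` matrix (no imputation; missing cells are an error).
Greenhouse–Geisser ε comes from the double-centred condition covariance,
`ε = tr(S̃)²/((k−1)·tr(S̃²))`, clamped to `[1/(k−1), 1]`, applied
multiplicatively to both dfs; p from the F distribution at the fractional
dfs. The effect size is **partial** eta squared,
`SS_effect/(SS_effect+SS_error)` — with a GG-corrected within-subject
design that is the conventional reading of a reported η², though a
classical η² interpretation cannot be ruled out. At k = 2 the ε estimate
is identically 1 and F equals the squared paired t (tested); the
implementation is also cross-checked against `car::Anova`'s GG machinery.

**Pairwise comparisons** use the pooled ANOVA error term:
`SE = sqrt(2·MS_error/n)` for every pair, `t = diff/SE` on `(n−1)(k−1)`
df, with both Bonferroni (×k(k−1)/2, capped at 1) and Holm adjustments
reported. This reproduces the reported t statistics exactly as printed
difference / printed SE.

**Correlations** are pairwise-deletion Pearson r with two-sided p from
the t transform — missing stress readings reduce n for stress pairs only.

## 5. The mediation model

Movement counts (swinging, rotating, sitting — all three jointly, one
path diagram) → shift-trial RT (mediator) → accuracy and stress
(outcomes). Equations are fitted by OLS, whose point estimates coincide
with ML under normal errors:

- mediator: `RT ~ swinging + rotating + sitting` (a paths),
- per outcome: `Y ~ RT + swinging + rotating + sitting` (b and direct
  c′ paths).

Indirect(X, Y) = a_X · b_Y and **total = direct + indirect by
construction**, an exact identity of the linear path model (asserted to
1e-10 on every fit). Rows with missing stress are excluded from the
stress equations only; the mediator equation keeps the full sample.
Standard errors are delta-method (Sobel for the indirect path; the
total-effect SE comes from the reduced-form regression `Y ~ X`, which for
complete-case outcomes equals direct + indirect exactly). Intervals are
bias-corrected percentile bootstrap over case resampling:
`z0 = Φ⁻¹(P(boot < estimate))` (clamped away from 0/1 when the bootstrap
distribution is degenerate), endpoints at `Φ(2·z0 ± z_{α/2})`. Resamples
with singular fits — or with too few complete stress rows — are skipped,
and the achieved resample count is reported rather than guessing a
correction; the same seed always reproduces identical intervals.
Standardised estimates refit the model on z-scored variables.

## 6. The Experiment-2 generators

**Subject tables.** Movement counts are normal draws at the observed
28-subject descriptives, *censored* at zero and rounded. (Censoring
rather than genuine truncation: left-truncating a distribution whose mass
sits 2 SDs above zero would inflate the swinging mean by about one count,
while censoring moves it ~0.15 — the censored mean is the one that
matches the reported descriptives.) RT, accuracy and stress follow the
linear path model with configurable planted coefficients; all defaults
are zero, making the default table a null data set. Accuracy is clamped
to [0, 1]; stress is left unclamped (its descriptives put negligible mass
below zero); stress goes missing with probability 2/28, the observed
missingness.

**Trial records.** Each subject gets 20 global, 20 local and 40 mixed
trials. The mixed kind sequence is built from a transition multiset with
shift and nonshift counts balanced to within one (39 transitions cannot
split evenly; which side gets the extra is random), shuffled, and walked
from a random starting level — balance by construction, matching a
half/half randomized design. Subject-condition means decompose into a
shared subject effect (sd 200 ms) plus a condition-specific deviation
sized so each condition's between-subject SD matches the reported SDs;
the unequal condition variances this produces are exactly the kind of
sphericity violation the GG correction exists for. Within a subject,
trial RTs are lognormal (positive, right-skewed — SDs alone cannot pin
the shape, and lognormal is the standard RT choice) with coefficient of
variation 0.2, moment-matched to the subject-condition mean. Correctness
is Bernoulli(0.968), the observed shift accuracy, applied to all
conditions. The generator does not model within-session autocorrelation
or practice effects.

At these defaults a 28-subject synthetic sample yields a GG-corrected F
around 20 with ε ≈ 0.5–0.7 and partial η² ≈ 0.4 — the same qualitative
regime as the motivating study — and the acceptance suite verifies that
the four-condition design rejects at α = 0.001 in ≥ 95% of replicates.

## 7. Problem sizes, tolerances, degenerate inputs

- Acceptance-level simulations use: 5 subjects × 60 s per activity for
  LOSO (full 300-epoch training per fold, ~25 s per fold); mediation
  recovery at n = 200 with 500 bootstrap resamples; null-coverage over
  100 replicate data sets at 500 resamples each. These sizes give stable
  pass/fail behaviour at the asserted thresholds while keeping a full
  test run in minutes on one CPU.
- Exact identities are asserted tightly: gravity-corrected means ≤ 1e-12,
  Parseval and pure-tone bins at 1e-9 relative, mediation decomposition
  at 1e-10, gradient checks at 1e-5 against central differences.
- Degenerate inputs fail loudly rather than silently: upsampling
  requests, missing ANOVA cells, singular designs, empty trial
  sequences, sub-window streams (empty result with a warning — the one
  soft failure, since a short recording is a data condition, not a
  programming error), and malformed sensor logs (parse errors name the
  offending line).

## 8. Known limitations

- The motion model is a stand-in: its amplitudes and axis conventions are
  internally consistent but cannot be validated against real recordings.
- Real-data quantities that depend on the original participant data (the
  per-participant LOSO accuracies, the observed F = 22.63, the observed
  mediation coefficients and correlation matrix) are not reproduction
  targets; the package asserts their internal arithmetic (mean of fold
  accuracies, df identities, t = diff/SE) and demonstrates the machinery
  on planted-effect synthetic data instead.
- The mediation model is linear with a single mediator; no
  exposure–mediator interaction, no latent-variable measurement model.
- The classifier is intentionally small and CPU-bound; no GPU path, no
  hyperparameter search, no CNN baseline.
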