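---
title: "Methods: sensor-driven fall-risk screening with tugfall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-driven fall-risk screening with tugfall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugfall)
```

## The screening problem

A geriatrician's fall-risk assessment synthesizes functional test
scores, medications, diagnoses and fall history into a binary label:
high risk ("faller") or low risk ("non-faller"). The Timed-Up-and-Go
(TUG) test compresses gait, balance, turning and transfer ability into
one number — the time to rise from a chair, walk 3 m, turn, walk back
and sit — and the standard screen calls a patient high-risk at 14 s or
more. Dichotomizing a continuous time is brittle: the decision flips on
a fraction of a second near the cutoff.

`tugfall` implements the alternative this package is built around:
record the *whole* TUG kinematic signal with wearable IMUs (tri-axial
accelerometer and gyroscope at the neck and both feet), and let a
classifier use the full time series rather than its duration alone. The
package covers every stage — synthetic cohort generation, signal
curation, segmentation, two classifier families, a bootstrap-bagging
evaluation protocol, and the clinical screening statistics used to
judge any of these screens against the clinician.

Throughout, **faller is the positive class and is coded 1**, and model
outputs are P(faller). Sensitivity is therefore the probability of
recognizing a high-risk patient, the quantity screening cares most
about; the decision threshold assigns the boundary p = 0.5 to the
faller class for the same reason.

## The synthetic cohort generator

Real clinical sensor recordings of this kind are typically not
redistributable, so the generator is a first-class module: it defines
the study conditions every downstream stage is developed and tested
under.

Each subject is a concatenation of five TUG phases — sit-to-stand, walk
out, turn, walk back, turn-and-sit — with durations drawn per class
from normal distributions (redrawn, with an incremented sub-seed, in
the rare case of a non-positive draw). On this skeleton the generator
places waveform templates:

* **Steps** as raised-cosine impulses at the subject's drawn cadence on
  the superior–inferior acceleration channel, with a weaker
  accompaniment on the anterior–posterior channel and a pitch-rate
  pulse per step. Inter-step intervals have a configurable coefficient
  of variation. Odd steps belong to the left foot and even steps to the
  right, so each foot sensor sees every second step at full amplitude
  while the neck sees the superposition at reduced amplitude — this is
  what makes sensor-location comparisons meaningful.
* **Sway** as a sinusoid at half the cadence on the mediolateral
  acceleration and roll-rate channels, scaled by a per-class gain.
* **Turns** as half-sine yaw-rate lobes whose amplitude integrates to a
  180° turn over the drawn turn duration.
* **Transfers** (sit-to-stand, stand-to-sit) as biphasic pitch-rate
  pulses with a superior–inferior transient.

White Gaussian noise is added per modality and the result is clipped
exactly to the sensor ranges (±16 G, ±2000 degree/s at 250 Hz — the
acquisition constants of the emulated hardware).

### Default class effects

No per-class kinematic effect sizes are published for this design, so
the defaults are chosen once as plausible for a geriatric clinic
population and are free parameters, not estimates:

| parameter | non-faller | faller |
|---|---|---|
| phase duration means (s) | 1.5, 3.2, 1.5, 3.2, 2.0 (total 11.4) | 2.5, 5.0, 2.5, 5.0, 3.2 (total 18.2) |
| cadence (steps/s) | 1.9 ± 0.12 | 1.45 ± 0.18 |
| step-time CV | 0.05 | 0.17 |
| mediolateral sway gain | 1.0 | 2.0 |

The duration distributions deliberately overlap (≈22% overlap
coefficient): a cohort whose classes are perfectly separated by total
duration alone would make every classifier trivially perfect and the
evaluation meaningless. The `preset = "strong"` parameter set widens
every contrast (cadence 2.0 vs 1.2, sway gain 3, step CV 0.25, lower
noise); it is the "strongly separated cohort" used by the power checks
in the test suite and the acceptance script, where the question is
whether the pipeline can recover structure that is known to be there.

What the generator does **not** emulate: gravity components and sensor
orientation drift, walking aids, double-support timing, inter-sensor
clock skew, and any validated biomechanics. Passing tests on synthetic
cohorts therefore demonstrate the statistical machinery — segmentation
bookkeeping, leakage-free splitting, calibrated metrics — not clinical
performance on real patients.

## Signal curation

The chain is **resample → normalize → pad**, in that order.

1. **Fourier resampling to 100 Hz.** Each channel's DFT is truncated at
   the new Nyquist frequency (50 Hz) and inverted at the new rate —
   the classical FFT resampling algorithm. This is simultaneously the
   low-pass filter and the downsampler; sub-Nyquist energy is preserved
   (the suite checks Parseval to within 1%). Implemented directly on
   `stats::fft` because the polyphase-FIR `resample` available
   elsewhere in R is a different algorithm with passband ripple.
2. **Min–max normalization per modality.** One global minimum and
   maximum over *all* samples, channels, locations and subjects in
   scope maps acceleration and angular velocity separately to [0, 1].
   Extremes are taken over signed values, not magnitudes: a magnitude
   range could not recover sign when mapping to [0, 1]. The default
   scope is `all_subjects`, reproducing the common (leaky) practice of
   normalizing before splitting; `train_only` is offered as the
   statistically sound alternative, in which test-set values may fall
   outside [0, 1] and are deliberately *not* clipped (a warning counts
   them).
3. **Zero-padding.** Zeros are appended so every recording matches the
   longest one, rounded up to a whole second. The rounding is a design
   choice the windowing relies on: with integer-second windows and
   strides, the sliding grid then lands exactly on the padded end, so
   every real sample falls inside at least one window and no partial
   window is ever needed. The unpadded length per subject is retained.

Padding zeros equal the normalized value of the modality minimum, so
windows that lie entirely in the padded tail carry no subject
information. They are flagged and dropped by default
(`drop_padding = FALSE` keeps them for sensitivity analyses).

## Segmentation and features

Windows are 3 s long with a 1 s stride: `floor((L − 3)/1) + 1` windows
per recording, starting at whole seconds from zero. Each window is a
`300 × 3` matrix (one modality at 100 Hz) labeled with its subject's
class — the CNN input.

The SVM instead receives nine numbers per subject: mean, population
standard deviation, and coefficient of variation (sd/mean) of each of
the three channels, computed **over the unpadded extent only** (padding
zeros would corrupt the means). A mean below 10⁻⁸ in magnitude makes
the CV numerically meaningless; it is reported as 0 with a warning
rather than an astronomical ratio.

## Classifiers

### The 1-D CNN

Architecture: four blocks of (1-D convolution → batch normalization →
ReLU), max-pooling of width 2 after blocks 2 and 4, flatten, one fully
connected unit, sigmoid. With the default valid convolutions a 300 × 3
window flows 300 → 296 → 292 → 146 → 142 → 138 → 69 → 69·F₄ → 1.

No deep-learning runtime is assumed: the network is implemented on
BLAS matrix operations. Convolutions are im2col matrix products (the
tap-gather and its adjoint, plus the batch-norm column broadcasts, are
small compiled kernels), training is Adam on binary cross-entropy, and
batch-norm keeps running statistics (momentum 0.1, ε = 10⁻⁵) for
inference. The convolutions carry no bias term — batch normalization
recentres every feature map immediately, making a conv bias exactly
redundant; the BN shift β is the effective bias. Correctness of the
hand-written backpropagation is enforced by a finite-difference
gradient check in the test suite, and training is bit-reproducible
given the configuration seed (initialization and shuffling share one
restored RNG stream).

Unpublished hyperparameters are free choices with these defaults:
filters (32, 32, 64, 64), kernels 5, pool 2, Adam 10⁻³, batch 64, 30
epochs. The bagging runs in the tests and acceptance script use a
smaller instance — filters (8, 8, 16, 16), 8 epochs, batch 96 — sized
so a 20-iteration bagging run on a 40-subject cohort completes in a
few minutes on one CPU; at the strong-separation conditions this
instance already saturates discrimination, so the extra capacity of
the default would only add runtime.

### The SVM baseline

An RBF-kernel SVM (`e1071`, standardized features, C = 1) on the
9-dimensional summary vectors. For ROC analysis its decision margin is
oriented so larger means more faller-like and mapped through the
logistic to (0, 1). The SVM sees only channel-level moments — exactly
the information bottleneck the CNN is meant to bypass.

## The bagging protocol

1. Split subjects 80/20, stratified by class, **once** (the default;
   `resplit_each_iter` redraws the split every iteration — the
   protocol description is ambiguous on this point, and splitting once
   isolates the resampling variance the CIs are meant to show).
   Per-class test counts round half up, so 53/45 fallers/non-fallers
   give an 11 + 9 test set. Splitting is at subject level; a leakage
   assertion verifies train and test subjects never overlap.
2. Per iteration *b* (seeded `master_seed + b`, so iterations are
   order-independent): resample the train set and the test set with
   replacement to `resample_factor ×` their sizes. The *multiset*
   defines the data: a subject drawn k times contributes its windows k
   times to training and to evaluation. Iterations whose multiset
   degenerates to one class are redrawn (≤10 times, logged).
3. Train on the training multiset's windows, predict P(faller) for the
   test multiset's windows, and compute Acc, Se, Sp, J, F1 at
   threshold 0.5 plus the Mann–Whitney AUC. `eval_level = "segment"`
   (default) scores windows directly; `"subject"` first averages each
   subject's window probabilities.
4. Report each metric's mean and percentile (2.5%, 97.5%) interval
   across iterations.

The C-statistic reported with a bagging summary is
z = (mean AUC − 0.5) / (sd(AUC)/√B) with the matching
mean ± 1.96·SE interval — an across-iteration test that the *average*
discrimination exceeds chance, which is the presentation convention
this protocol pairs with percentile CIs. For a single score set,
`c_statistic_test()` provides the classical Hanley–McNeil standard
error instead; the two answer different questions and both are exposed.

The traditional-TUG comparator needs no training: per iteration it
selects 10 fallers and 10 non-fallers without replacement, draws 2000
(100 × 20) subjects with replacement from them, classifies by
TUG time ≥ 14 s, and aggregates identically (small cohorts cap the
per-class selection at the available class size, scaling the draw
count as 100 × set size).

## Clinical screening statistics

* Confusion matrices with faller positive; Acc, Se, Sp, F1, and
  Youden's J = Se + Sp − 1. Metrics with zero denominators are `NA`,
  never a silent zero.
* Dichotomization rules carry an explicit direction — TUG ≥ 14 s,
  4-stage balance ≤ 30 s, 30-second chair stand ≤ 8 stands all predict
  faller — with inclusive boundaries in both directions.
* The J-optimal cutoff sweeps the sorted unique observed values (no
  invented grid); ties break toward higher sensitivity, then the lower
  cutoff.
* ROC AUC is the Mann–Whitney concordance probability with ties
  counted ½, computed by midranks and property-tested against
  brute-force pair enumeration.
* Odds ratios use the cross-product with the Woolf (log) confidence
  interval; a single zero cell triggers the Haldane–Anscombe 0.5
  correction (flagged), two zero cells in a line yield an `NA`
  sentinel.

## Numerical and design notes

* All randomness flows through seeds; every stochastic function
  restores the caller's RNG state. Per-subject and per-iteration seeds
  derive from master seeds so results are independent of execution
  order.
* Fourier resampling handles the even-length Nyquist bin by folding
  (downsampling) or symmetric splitting (upsampling), preserving
  realness and DC exactly.
* The pipeline orchestrator (`run_experiment`) validates its
  configuration before any computation, labels any stage failure with
  the stage name, and can cache the simulated + preprocessed cohort
  keyed by an md5 of the generating options.
* Problem sizes in the shipped checks — 40 subjects and 20 bootstrap
  iterations for the CNN power check, 10 iterations for the
  label-shuffled null, 98 subjects for the comparator — are the
  package's chosen demonstration scale: large enough for stable means,
  small enough to run routinely.

## Known limitations

* The generator's class effects are stylized; effect sizes are not
  calibrated to any real cohort, and synthetic separability says
  nothing about real-world AUC.
* Segment-level evaluation scores windows, not patients; the
  subject-level option is provided but aggregation by simple averaging
  is itself a modeling choice.
* The all-subjects normalization scope reproduces a leaky but common
  practice; use `train_only` for honest generalization estimates.
* Batch-norm statistics are per-batch during training; very small
  final batches add gradient noise (batches are shuffled each epoch,
  so no window is systematically last).
* The Hanley–McNeil standard error is asymptotic and conservative near
  AUC ∈ {0, 1}; degenerate cases are flagged and their CIs clipped.
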