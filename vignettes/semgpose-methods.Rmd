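---
title: "Cross-trial sEMG gesture recognition: models, training scheme and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trial sEMG gesture recognition: models, training scheme and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface electromyography (sEMG) records the electrical activity of skeletal
muscle from skin electrodes. A muscle–computer interface classifies short
signal windows into hand gestures. The practically important failure mode is
*cross-trial* degradation: a classifier trained on some repetitions (trials)
of each gesture performs worse on later repetitions of the same subject,
because trial-to-trial nuisance factors — electrode impedance and position
drift, contraction intensity, fatigue — shift the signal distribution while
the gesture stays the same. `semgpose` implements a classifier and a
two-stage training scheme built around this problem, together with a
synthetic trial simulator so that the whole pipeline is testable without any
recording hardware or dataset download.

## The classifier

The window classifier is a dual-stream convolutional network over a
`W x C` window (`W` time samples, `C` electrodes):

* a **temporal stream**: two blocks of 1D convolution over the time axis
  with all `C` electrodes as input channels, each followed by batch
  normalization and ReLU. The temporal kernel extent defaults to `W/2`
  rounded to odd, in the spirit of multivariate-time-series CNNs that use
  large fractional-length kernels;
* a **spatial stream**: the window viewed as a one-channel `W x C` image,
  passed through two 3x3 2D convolutions and then two 1x1 *locally
  connected* layers (convolutions without weight sharing across positions),
  with dropout. Locally connected layers let each electrode–time position
  learn its own weights, which suits the fixed spatial layout of an
  electrode array;
* **fusion**: the spatial stream is collapsed to a per-time-position
  feature vector (electrode axis folded into the feature axis) and
  concatenated with the temporal stream, so the fused feature dimension is
  `temporal_filters + C * spatial_filters`. It grows linearly with the
  electrode count, and with it the parameter count of the next stage;
* a **four-head self-attention layer** over time tokens with a residual
  connection and a position-wise feedforward layer. Because the attention
  projections act on the fused (electrode-bearing) feature axis, their
  parameter count increases with `C` — which is why this design targets
  sparse (few-electrode) arrays;
* one further 1D convolution block, global average pooling over time, and
  an affine map to `N` gesture logits.

Two independent affine + tanh projection heads map the pooled feature to a
*gesture-relevant* representation `u` and a *trial-relevant* representation
`v`, both of length `d` (default 128). All weights start from
Xavier-uniform initialization.

## The two-stage training scheme

**Stage 1 — cross-trial mutual-information maximization.** Trials of the
same subject and gesture are aligned by truncation to their minimum length
(the tail of the ending phase is discarded), so a time step indexes the same
movement phase in every trial. For each anchor window at time step `t` of
trial `i`, a positive window is drawn at the same `t` from a uniformly
random other trial `j`. The encoder maximizes

* an InfoNCE lower bound between two lightly jittered encodings of the same
  window (the "self" term, on the concatenated `[u; v]` joint
  representation), and
* `lambda1` times an InfoNCE bound between `u_i^t` and `u_j^t` across the
  trial pair (the cross-trial term),

while minimizing `lambda2` times a CLUB upper bound on `I(u; v)`. CLUB
needs the conditional `p(v|u)`, which is unavailable; a two-layer
likelihood estimator `Q` predicts a diagonal Gaussian `q(v|u)` and is
fitted by maximum likelihood in alternation with the encoder (one `Q` step
per encoder step). Both use plain SGD: encoder at 0.001, `Q` at 0.005,
batch 128, 30 epochs at full scale.

InfoNCE uses cosine-similarity logits at temperature 0.1. The estimate is
capped at `log B` for batch size `B` by construction, and under
independence it is a *lower* bound on zero mutual information, so its
Monte-Carlo distribution sits slightly below zero — most visibly at sharp
temperatures, where the random-critic variance inflates the contrastive
cross-entropy. The test suite asserts exactly this one-sided behaviour
rather than symmetric closeness to zero.

**Stage 2 — cross-modal knowledge distillation.** Hand movements are far
more stereotyped across trials than the sEMG signal that drives them, so a
pose-based classifier is an excellent teacher for cross-trial invariance. A
reduced XceptionTime-style network (two Inception-style multi-kernel 1D
convolution blocks with residual connections) is trained with supervision
on pose windows aligned sample-by-sample to the sEMG windows. The student —
the sEMG encoder initialized from stage 1 plus a classification head — then
minimizes `(1 - alpha) * CE + alpha * KL`, where the KL term compares the
teacher's temperature-`T` softened distribution on the pose window covering
the same sample interval against the student's. Defaults: `T = 1`,
`alpha = 0.5`, SGD at 0.1 with x0.1 drops at epochs 16 and 24, 28 epochs at
full scale. The teacher is frozen during distillation; no `T^2` gradient
scaling is applied to the KL term (the objective is the plain convex
combination). Inference uses sEMG only.

## The synthetic study conditions

The simulator emulates the statistical structure the scheme relies on, with
defaults fixed once:

* 2 subjects x 8 gestures x 6 trials, 10 electrodes at 100 Hz, 2.0 s
  trials (a compact DB1-like geometry);
* each trial has three phases — making, holding, ending the gesture — with
  fractions (0.25, 0.50, 0.25); per (gesture, channel) peak amplitudes are
  drawn once per dataset, giving each gesture a fixed spatial activation
  pattern;
* the carrier is band-limited white Gaussian noise, amplitude-modulated by
  the trapezoidal phase envelope — a standard first-order sEMG surrogate
  with no motor-unit physiology;
* cross-trial nuisances: per-trial multiplicative gain `LogNormal(0, 0.2)`,
  a one-position circular electrode shift with probability 0.2, additive
  sensor noise of sd 0.3, and ±5% trial-length jitter (which is what makes
  minimum-length alignment meaningful);
* pose streams: 15 joints, one unit quaternion per joint per sample,
  synthesized by spherical interpolation (slerp) from the neutral pose to a
  fixed per-gesture ending pose across the make phase, held, then slerped
  back. The ending-pose dictionary is synthetic and deterministic; it is a
  stand-in, not a model of glove-measured kinematics. Pose streams are
  deterministic per gesture, mirroring pseudo-pose generation for datasets
  without glove recordings — so the teacher can in principle reach perfect
  training accuracy, which is exactly the property that makes it a useful
  soft-target source.

What the simulator does *not* model: motor-unit action potentials,
force/kinematics dynamics, inter-subject anatomy, nonstationary fatigue
drift. Passing tests on this data demonstrate that the training machinery
behaves as designed (estimator calibration, scheme ordering, invariance
trends); they are not evidence about accuracy on real recordings.

## Preprocessing choices

The package implements both filter families used for NinaPro-style data: a
zero-phase low-pass Butterworth (default order 1, cutoff 1 Hz) and a moving
RMS envelope. Which one is appropriate depends on what the recording
encodes. Low-rate NinaPro DB1 signals are already envelope-encoded by the
acquisition device, so a 1 Hz low-pass denoises them. The simulator, by
contrast, emits raw zero-mean oscillating carriers; a 1 Hz low-pass of such
a signal destroys the amplitude information that carries the class signal,
so the pipeline default is the RMS envelope with a 100 ms window at 100 Hz
(20 ms is the conventional choice at kHz rates). Zero-phase filtering is
implemented with odd-reflection padding and steady-state initial
conditions, so constants pass exactly; plain forward-backward filtering
from zero initial state would leave large edge transients at low cutoffs.

After filtering, each trial is scaled by its maximum absolute value
(zero-signal trials are left untouched) and mu-law companded with mu = 256:
`T(x) = sign(x) ln(1 + mu |x|) / ln(1 + mu)`, an odd, strictly monotone map
of `[-1, 1]` onto itself that expands low-amplitude structure. Windows are
200 ms with half-open `[t, t + W)` intervals, 0-based start indices, and a
default stride of 100 ms for the synthetic data (10 ms is typical for
full-scale DB1 work; the coarser stride keeps the simulated problem sizes
small). The window label is the trial's single gesture label.

## Problem sizes used by the tests and the acceptance script

The full-scale defaults (64 filters per stream, `d = 128`, 30 + 28 epochs)
are what a practitioner would use on a real database. The shipped checks
run a compact configuration chosen once for the synthetic conditions: 8
temporal filters, 4 spatial filters, `d = 16`, dropout 0.1, stage 1 for 3
epochs, stage 2 for 8 epochs, three seeds, with the DB2-style 1,3,4,6 /
2,5 trial split. On these sizes the four-scheme ablation retrains all
pipelines from scratch in a few minutes on one CPU core. The CLUB
calibration uses jointly Gaussian pairs with per-dimension correlation
rho, `d = 4`, `n = 10^4`, against the closed form
`-(d/2) ln(1 - rho^2)`.

## Numerical and design notes

* **Autodiff.** No deep-learning framework is assumed: the package carries
  a small reverse-mode tape over numeric matrices (im2col convolutions,
  batched attention, batch-norm, the contrastive and distillation losses).
  Every layer's gradient is verified against central finite differences in
  the test suite. One caveat of such checks: with zero-initialized biases,
  ReLU inputs can sit exactly at the kink, where the subgradient convention
  and a symmetric difference quotient legitimately disagree — the checks
  therefore perturb parameters away from zero first.
* **Determinism.** All randomness flows through R's RNG; every training
  entry point seeds it once, so fits are bitwise-reproducible on one
  thread. The per-gesture ending-pose dictionary uses a private seed and
  restores the caller's RNG state.
* **Alignment and pairing.** Trials are truncated to the group minimum
  length from the end. One positive is drawn per anchor per epoch and
  resampled every epoch (the pairing multiplicity is not dictated by the
  protocol; resampling increases pair diversity at no cost). Mismatched
  CLUB pairs use a uniform in-batch shuffle, which allows self-matches with
  probability `1/B` — an unbiased sample from the product of marginals.
* **"u ⊙ v" joint representation.** The self term treats the joint
  representation as the concatenation `[u; v]` of the two heads' outputs,
  and realizes the intractable MI with the raw window as InfoNCE between
  two independently jittered encodings (channel-independent Gaussian
  jitter, sd 0.01).
* **Loss weights.** `lambda1 = 1`, `lambda2 = 0.1` by default; both are
  config-exposed, as is the InfoNCE temperature.
* **Teacher/student alignment.** Teacher logits are computed on the pose
  window covering exactly the same sample interval as the student's sEMG
  window; this is the only pairing rule consistent with per-sample-aligned
  pose streams.
* **Degenerate inputs.** Trials shorter than one window yield empty window
  sets; single-trial groups are skipped with a warning by the pair sampler;
  zero-signal trials survive normalization unchanged; subjects without test
  windows are dropped from evaluation with a warning; an all-zero paired
  difference vector is a degenerate Wilcoxon comparison and raises an
  error.
* **Wilcoxon test.** Exact enumeration of the `2^n` sign patterns
  (conditional on observed midranks, so ties are exact) for `n <= 15`,
  normal approximation with tie correction above. `stats::wilcox.test`
  serves as an independent cross-check in the tests, not as the
  implementation.
* **MAT files.** A minimal MAT level-5 reader/writer (uncompressed,
  little-endian, numeric arrays) ships with the package — enough to
  round-trip NinaPro-style `emg`/`(re)stimulus`/`(re)repetition`/`glove`
  recordings. The v7.3/HDF5 MAT dialect and compressed elements are not
  supported.

## Known limitations

* The representation heads inherit a common-mode component from the
  ReLU/global-average-pooling pipeline: at initialization, `u` vectors of
  *all* windows are highly mutually similar (cosine near 0.9). Contrastive
  training first destroys this collapse (spreading representations over the
  sphere) before alignment can raise the matched-pair similarity, so at
  very short pretraining budgets the absolute matched-pair cosine can sit
  below its collapsed initial value even while the *relative* invariance
  (matched-pair minus random-pair similarity) improves. The ablation
  harness therefore records both the absolute and the relative diagnostic.
* The simulator's class signal is carried by channel-amplitude patterns,
  so simple envelope statistics are strong baselines; the deep pipeline's
  value on this data is in exercising the training machinery, not in
  beating those baselines at tiny scale.
* Real NinaPro MAT files in the v7.3 (HDF5) dialect require conversion to
  uncompressed v5 before import.
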