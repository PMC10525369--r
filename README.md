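# semgpose

Cross-trial gesture recognition from sparse multichannel surface
electromyography (sEMG), for researchers building muscle–computer
interfaces. The practical obstacle in this setting is *cross-trial* drift:
a classifier trained on some repetitions (trials) of each gesture degrades
on held-out repetitions of the same subject, because electrode contact,
contraction intensity and fatigue shift the signal between trials while
the gesture stays the same.

`semgpose` implements, in pure R:

* **sEMGXCM**, a dual-stream window classifier: a temporal stream (1D
  convolutions over time with the C electrodes as input channels) and a
  spatial stream (2D convolutions plus 2D locally connected layers on the
  W × C window image), fused per time position and passed through a
  four-head self-attention layer with residual connection, a feedforward
  layer, a further convolution block, global average pooling and a softmax
  classifier. The fused feature dimension — and with it the attention
  layer's parameter count — grows with the electrode count, so the design
  targets sparse arrays.
* **sEMGPoseMIM**, a network-agnostic two-stage training scheme.
  *Stage 1* learns trial-invariant representations by maximizing mutual
  information between windows sampled at the same time step of different
  trials (InfoNCE lower bound, cosine similarity), while disentangling a
  gesture-relevant representation *u* from a trial-relevant representation
  *v* by minimizing a CLUB upper bound on I(u; v), with a learned diagonal
  Gaussian variational conditional q(v|u):

  min −[ I(x; u⊙v) + λ₁ I(uᵢᵗ; uⱼᵗ) ] + λ₂ L_inter(u; v),  L_inter = E log q(v|u) − E log q(v′|u)

  *Stage 2* trains a hand-pose teacher network (reduced XceptionTime-style)
  with supervision and distills it into the stage-1-initialized sEMG
  student: L = (1 − α)·CE + α·KL(pᵀ ‖ qᵀ) with temperature-T softened
  distributions. Inference uses sEMG only.
* a **synthetic trial simulator** (gesture-specific trapezoidal envelopes
  over make/hold/end phases modulating band-limited Gaussian carriers, with
  per-trial gain, electrode-shift and noise nuisances) plus aligned
  quaternion hand-pose streams synthesized by slerp — so the entire
  pipeline is testable with no dataset download;
* NinaPro-style preprocessing (Butterworth / moving-RMS filtering, mu-law
  normalization T(x) = sign(x)·ln(1 + μ|x|)/ln(1 + μ) with μ = 256, 200 ms
  sliding windows), trial alignment and cross-trial pair sampling,
  per-subject cross-trial evaluation with the standard DB1–DB7 trial-split
  presets, an exact Wilcoxon signed-rank test, MAT-file import/export, and
  a command-line interface (`inst/cli/semgpose`).

No deep-learning framework is required: the package carries its own small
reverse-mode autodiff core, with gradients verified against finite
differences in the test suite.

## Worked example

```r
library(semgpose)

ds <- generate_dataset(sim_config())   # 2 subjects x 8 gestures x 6 trials
print(ds)

fit <- semg_pose_mim(
  ds,
  model_config = model_config(n_channels = 10, window_len = 20, n_gestures = 8,
                              representation_dim = 16, temporal_filters = 8,
                              spatial_filters = 4, dropout = 0.1),
  split   = split_preset("db2"),       # train trials 1,3,4,6; test 2,5
  stage1  = stage1_config(epochs = 3),
  distill = distill_config(epochs = 8),
  seed    = 1)
summary(fit)
```

```
Synthetic sEMG dataset: 96 trials (2 subjects x 8 gestures x 6 trials)
  10 channels at 100 Hz, ~2 s per trial, 15 pose joints
Two-stage cross-trial sEMG gesture recognizer
  8 gestures, 10 electrodes, 20-sample windows; 33,308 parameters
  stage 1: 3 epochs (MI pretraining); stage 2: 8 epochs (distillation, alpha = 0.5, T = 1)
  held-out cross-trial accuracy: 53.6% (trials 2,5)

Per-subject held-out accuracy:
  subject 1: 54.0%
  subject 2: 53.3%

Final stage-2 losses: CE 1.2359, KL 1.0473 (train acc 67.3%)
```

The held-out accuracy is the cross-trial metric: windows of trials 2 and 5
were never seen in training, so 53.6% against a chance level of 12.5%
(eight gestures) measures transfer across the simulated trial-to-trial
nuisances. Training from scratch on the identical data and seeds reaches
about 47% (see the ablation below) — the gap is what the two-stage scheme
buys. `predict(fit, windows)` classifies new windows from sEMG alone.

The four-scheme comparison (scratch / stage-1-only / stage-2-only /
two-stage) is available directly:

```r
run_ablation(ds, seeds = 1:3)   # data.frame shaped like a per-stage ablation table
```

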