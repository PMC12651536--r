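---
title: "Methods: strip-convolution attention networks for taste-EEG decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strip-convolution attention networks for taste-EEG decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding problem

Gustatory stimulation evokes scalp-measurable EEG responses whose intensity,
spatial extent and latency vary with stimulus concentration. The task
addressed here is multi-class decoding: given a single 1-s epoch of
21-channel EEG (10--20 montage, 256 Hz, so a 21 x 256 matrix), predict which
of six sweetness-concentration classes (class 0 = pure-water control,
classes 1--5 = increasing sucrose concentration) evoked it.

`tastenet` implements a compact convolutional classifier built around a
shape-preserving *feature-computation block* that combines four ideas:

1. **Multi-branch strip convolutions.** Each branch applies a 1 x k
   convolution along time followed by a k x 1 convolution across
   electrodes, with k = 3, 5, 7 over the three branches, so small and large
   receptive fields coexist. Both factors are stride-1 with symmetric zero
   padding (k-1)/2, so the electrode and time axes never change length.
2. **Channel and spatial attention gates.** A per-channel gate (global
   average pool, a length-3 one-dimensional convolution across channels
   with a single shared bias-free filter, then a sigmoid) rescales
   channels; a per-position gate (channel mean, 3 x 3 convolution, sigmoid)
   rescales positions. Both gates are strictly inside (0,1), so they can
   only attenuate, never amplify.
3. **Channel-token self-attention.** Three independent point-wise (1 x 1)
   convolutions project the gated map to Q, K, V, each flattened to
   C x (H*W) in a fixed electrode-major order; scaled dot-product attention
   `softmax(QK'/sqrt(d_k)) V` with `d_k = H*W` mixes the C channel tokens;
   the result is reshaped back with the same ordering. Attention is
   single-head, one pass per branch.
4. **Residual connections** around the local path (branch input added to
   the gated convolution output) and around the self-attention (its input
   added to Z).

Branch outputs are concatenated along channels and fused back to C channels
by a point-wise convolution, so a block maps C x H x W to C x H x W
exactly. The full network is: point-wise expansion of the raw 1 x 21 x 256
epoch to 40 channels, two blocks, point-wise reduction to 1 channel, 1 x 2
average pooling along time (256 -> 128), then dense layers of 128 and 6
units emitting logits.

## Numerical conventions and open choices

Where the architecture sketch leaves details open, the package makes these
choices (all switchable through configuration):

* **Convolution semantics.** Learned strip convolutions use true-convolution
  (kernel-flipped) semantics, so with a frozen kernel their output equals
  the centre crop of the textbook full 2-D convolution, which the package
  exposes as `conv2d_full()` and uses as its test oracle. For learned
  kernels the distinction is immaterial (the flip is absorbed into the
  weights); for verification it makes the contract exact.
* **Sigmoid.** The standard logistic `1/(1 + exp(-x))`; gates therefore lie
  strictly in (0,1).
* **Stabilisation.** Batch normalisation + ReLU follow each strip
  convolution by default; `strict_paper_mode = TRUE` removes them, leaving
  the bare pipeline. The stabilised variant is the default because the
  bare multi-branch block trains noticeably less reliably at learning rate
  0.01.
* **Component toggles.** Ablations decompose a branch into three component
  groups: the local path (strip convolutions plus both gates), the
  self-attention, and the residual additions. A residual connection with no
  partner component is rejected. The kernel-direction ablation restricts
  the local path to its 1 x k or k x 1 factor.
* **Softmax axis.** Rows of QK' (the key axis), the standard choice; every
  softmax row sums to 1.
* **Flatten order.** Electrode-major, time-minor, identical in the Q/K/V
  projection and the Z reshape. Any consistent order is equivalent;
  consistency is the contract and is what the round-trip tests pin down.
* **Reduction width.** The reduction point-wise convolution targets 1
  channel by default (the lightest head: the flattened map is
  21 x 128 = 2688); the width is configurable.
* **Pooling.** Non-overlapping 1 x 2 windows (stride 2) along time, mean by
  default, max available.
* **Initialisation.** All learnable tensors draw from the uniform fan-in
  scheme U(-1/sqrt(fan_in), 1/sqrt(fan_in)) under a configuration seed;
  two builds from one configuration are bit-identical.
* **Optimisation.** Cross-entropy with Adam at learning rate 0.01; "500
  iterations" is read as 500 epochs. Gradients are computed by an analytic
  backward pass through every layer (verified against central finite
  differences in the test suite); batches may be split into micro-batches
  with gradient accumulation, which changes memory use but not results.
* **Best-fold selection.** After stratified k-fold cross-validation the
  fold model with the highest validation accuracy is kept; ties break to
  the lowest fold index. Undefined precision/recall (empty denominator)
  reports 0 with a warning.
* **Cross-validation stratification.** Folds stratify by class only. Epochs
  cut from one recording can therefore land on both sides of a fold
  boundary; `stratified_split(grouped_by_subject = TRUE)` is provided for
  leakage-free subject-level splits.

## The synthetic generator

No public recordings accompany the acquisition protocol the package
targets, so `tastenet` ships a parametric generator whose defaults encode
the protocol: 20 subjects x 6 classes x 6 repetitions x 15-s recordings at
256 Hz, band-passed 0.5--45 Hz (zero-phase 4th-order Butterworth, applied
to the continuous recording *before* segmentation so epoch edges carry no
filter transients) and cut into 1-s epochs -- 10,800 samples of 21 x 256.

Each recording is 1/f background noise (FFT-shaped Gaussian noise, slope
-1, SD 0.5 a.u.) plus, for classes >= 1, an evoked 8-Hz oscillation:

```
signal_e(t) = pink_e(t) + g_subj * gain[class] * w_e(class)
              * env(t; onset[class]) * sin(2*pi*8*t + phi)
```

* `gain` rises linearly 0.5 -> 2.5 over classes 1--5 (class 0 has no evoked
  term), encoding the finding that activation intensity grows with
  concentration;
* `w_e` is a Gaussian decay of each electrode's distance from the nearest
  focus (C3, C4, Cz, T3, T4) with a per-class scale rising 0.5 -> 1.5,
  encoding the growing spatial spread (electrode geometry comes from a
  schematic 2-D 10--20 layout table; only relative distances matter);
* `env` ramps from 0 to 1 over 100 ms starting at a per-class onset latency
  falling 0.20 -> 0.05 s, encoding faster onsets at higher concentration;
* `g_subj` is a per-subject lognormal gain (log-SD 0.15) and `phi` a random
  per-recording phase.

The noise SD (0.5 a.u. against evoked amplitudes up to 2.5) was chosen once
so that the class structure dominates but a visible noise floor remains;
the generator makes no claim of physiological signal-to-noise realism, and
carries no artefact models (blinks, EMG), no source-space simulation and no
inter-electrode noise correlation. Tests passing on this generator
therefore demonstrate that the pipeline can learn exactly the structure the
generator encodes (amplitude/spread/onset gradients) -- not that it would
reach any particular accuracy on real gustatory EEG.

Given the spec seed, generation is bit-reproducible; every (subject, class,
repetition) triple derives its own stream from the base seed, so any
recording can be regenerated in isolation.

## Problem sizes used by the tests and the acceptance script

The defaults of record (40 channels, 2 blocks, 500 epochs, batch 200,
10-fold CV on 10,800 samples) describe the full-scale experiment. For
routine verification the package defines a *desk profile*, chosen once as
the smallest setting at which the learning problem remains non-trivial and
training converges: 360 samples (4 subjects x 6 classes x 1 repetition x 15
epochs), 8 expansion channels, one block, 12 epochs of Adam at batch 32,
2-fold cross-validation. A desk training run takes on the order of a minute
on one CPU core. The learning-sanity check (held-out accuracy >= 90% in at
least 4 of 5 seeds) and the ablation-ordering check (full block >=
conv-only single branch, 3 seeds) both run at this profile; the ablation
comparison uses 5-epoch runs since only the ordering, not the absolute
level, is at stake. The structural-grid check exercises the channel axis
(10--80, one block), the block axis (1--5 at 10 channels) and the largest
corner (80 channels, 5 blocks) rather than the full 8 x 5 cross, which adds
cost without adding coverage.

## Known limitations

* The engine is CPU-only, double precision, and sized for the desk profile;
  full-scale training (500 epochs on 10,800 samples at 40 channels) is
  expressible but slow in this implementation.
* Batch-normalisation statistics are global over a batch, so training and
  small-batch evaluation can differ slightly; evaluation always uses
  running moments.
* The generator's separability is by construction; accuracy numbers
  obtained on it are not comparable to accuracies on human recordings.
* Baseline architectures (LeNet-5, MobileNet V2, ...) are out of scope; the
  harness evaluates any object that implements the `forward()` contract.
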