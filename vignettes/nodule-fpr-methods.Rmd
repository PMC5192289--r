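---
title: "Methods: a convolutional network for nodule false-positive reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a convolutional network for nodule false-positive reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A lung CAD pipeline first detects nodule candidates on thoracic CT with high
sensitivity, which inevitably flags many vessel cross-sections and other
nonnodule structures. The false-positive-reduction (FPR) stage is a binary
classifier that re-examines each candidate's region of interest (ROI) and
keeps true nodules — solid, semisolid and ground-glass-opacity (GGO)
appearances alike — while discarding false alarms. `noduleCNN` implements
that stage as a compact convolutional network operating directly on
normalized 32x32 pixel patches, with no hand-crafted features.

## ROI extraction

Annotations come as freehand contours (nodules with a measurable margin) or
single centroid marks (small nodules and nonnodules). For each region we

1. take the geometric center as the vertex mean of the contour, rounded
   half-up per axis;
2. measure the bounding-box extent (`max - min + 1` per axis);
3. cut a 32x32 crop centered there if the extent fits within 32x32 on both
   axes, otherwise a 64x64 crop that is mean-downsampled 2x2 back to 32x32;
4. map raw intensities into `[0, 1]` through a fixed linear window.

Several conventions here are deliberate package choices where the procedure
itself is underdetermined:

* **Even-window centering.** A size-32 crop centered at `c` covers the
  half-open range `[c - 16, c + 16)`; coordinates are 0-based with
  pixel-center semantics. Any convention shifts every patch by at most one
  pixel; fixing one makes extraction reproducible.
* **Edge handling.** Crops reaching past the slice are padded with the
  normalization window floor (air-equivalent), so border candidates are
  usable rather than dropped.
* **Downsampling.** 2x2 mean pooling is used rather than interpolation
  because it preserves the image mean exactly — a property the test suite
  asserts bit-for-bit.
* **Normalization.** A fixed linear window, not per-patch min-max, so that
  identical tissue maps to identical inputs across patches and exams. For
  calibrated Hounsfield-unit arrays a `c(-1000, 400)` lung window is the
  conventional setting; fixtures already stored in `[0, 1]` use the identity
  window. Slices are accepted as in-memory matrices or grayscale PNG; no
  DICOM reader is bundled, so HU arrays are expected to be decoded upstream.

## Network

The default 32x32 architecture is

```
input 32x32 (1024 units)
conv 8 @ 5x5, stride 1, ReLU   -> 28x28x8  (6272)
maxpool 2x2, stride 2          -> 14x14x8  (1568)
conv 16 @ 5x5, stride 1, ReLU  -> 10x10x16 (1600)
maxpool 2x2, stride 2          -> 5x5x16   (400)
fc 150, ReLU -> fc 100, ReLU -> fc 50, ReLU -> fc 2
softmax over (nodule, nonnodule)
```

Convolutions are unpadded ("valid"): that is the only placement under which
the 32 → 28 → 14 → 10 → 5 chain and the unit counts 6272, 1568 and 1600
arise with 5x5 kernels and 2x2/2 pooling. Note the count after the
second pooling layer is 16·5·5 = 400 by shape arithmetic; `infer_shapes()`
reports that arithmetic value. Orientation is cross-correlation (no kernel
flip), the universal CNN convention; with learned kernels the flipped and
unflipped parameterizations are equivalent.

Choices the architecture description leaves open, resolved as package
defaults:

* **Loss.** The output layer is a softmax probability pair, trained with
  cross-entropy — the canonical pairing, whose combined gradient collapses
  to `probs - one_hot(label)`.
* **ReLU placement.** After both convolutions and the 150/100/50 fc layers;
  the final 2-node layer emits raw logits so the softmax sees an
  unconstrained score.
* **Initialization.** Fan-scaled uniform weights with bound
  `sqrt(6 / (fan_in + fan_out))`, zero biases, always from an explicit seed.
* **Tie prediction.** An exact (0.5, 0.5) tie is called nonnodule — the
  conservative call for a stage whose purpose is removing false positives.
* **64x64 inputs.** The layer kinds generalize, but no published default
  parameterization exists for the larger input, so the package exposes the
  64x64 variant only through a user-specified `network_config()`.

### Numerical safeguards

Softmax subtracts the maximum logit before exponentiating; cross-entropy
clamps probabilities to `[1e-12, 1]`. All accumulation is in double
precision. Max-pool ties go to the first window position in row-major
order, and that position receives the entire routed gradient, so gradient
mass is conserved exactly.

### Gradient verification

Every backward pass is checked against central differences
(`numeric_gradient_check()`), with the deviation measured as
`|analytic - numeric| / max(|analytic|, |numeric|, eps)`. Layer-level checks
run on randomized small shapes with inputs jittered away from ReLU kinks
and pooling ties, where the derivative exists; the full-network check
samples coordinates across every parameter tensor rather than sweeping all
~8.3e4 parameters, keeping the oracle cost bounded while still touching
each layer.

## Training

Plain minibatch SGD with classical momentum:
`v <- mu * v - eta * g; w <- w + v`. Defaults: `eta = 5e-4`, `mu = 0.9`,
batch size 32 (averaged gradients), at most 50 epochs. The dataset is
reshuffled from the seeded RNG at the start of every epoch.

Two schedules are provided. `constant` never changes the rate (the
cross-validation protocol). `decay_on_precision` multiplies the rate by 5/6
at the end of each epoch once training precision has first reached 0.85
(the holdout protocol), so after `d` post-threshold epochs the rate is
`eta0 * (5/6)^d`. Ambiguities resolved as defaults: "precision" is
training-set classification accuracy; the trigger is latched (decay keeps
firing even if precision later dips); a `one_shot` mode performing a single
decay is available for users who read the rule the other way.

Termination: the epoch cap, or training precision reaching
`target_accuracy`, or a concrete convergence rule — mean-loss improvement
below 1e-6 for five consecutive epochs. A non-finite loss aborts with the
history attached for diagnosis.

## Evaluation

* `run_cf_test()`: seeded k-fold cross-validation (k = 10 by convention),
  k models trained from derived seeds, confusion counts pooled across folds
  (micro-average) for the headline report, per-fold reports kept.
* `run_dd_test()`: one seeded split with 85.7% for training (half-up
  rounding of `0.857 n`), the test side frozen, and the full metric set
  recomputed after every epoch, giving per-iteration trajectories.

Metrics: accuracy, sensitivity `TP/(TP+FN)`, F-measure taken as F1 (the
harmonic mean of precision and sensitivity; the name alone does not pin a
beta, and F1 is the field default), and FP/exam with the denominator
defined as the number of distinct exams contributing patches to the
evaluated set. Zero-denominator ratios are reported as 0 with a
`degenerate` flag rather than NaN. Splits default to patch-level
randomization; `by_exam` grouping is available because patch-level splits
let two patches of one exam straddle train and test, which leaks
exam-level appearance — worth knowing even though plain splits remain the
default protocol.

## Synthetic data

`generate_dataset()` emulates the classes the classifier must separate:

| kind | label | construction |
|---|---|---|
| solid | 1 | compact bright Gaussian blob (sigma 2.5-4 px) |
| semisolid | 1 | wide moderate blob plus brighter off-center core |
| ggo | 1 | wide (sigma 6-9 px) low-contrast blob |
| vessel | 0 | anisotropic ridge, long/short sigma ratio ~5-10, random angle |
| background | 0 | faint symmetric wide fluctuations |

All classes sit on a 0.35 background with Gaussian pixel noise and are
clamped to `[0, 1]`. `separation` scales signal amplitude against noise
(contrast-to-noise roughly 10 / 2 / 0.2 for high / medium / low); at `low`
the classes are practically indistinguishable, and held-out accuracy near
0.5 on balanced low-separation data is itself a test that no label
information leaks through the generator. Class imbalance defaults to the
40772 : 21720 nodule : nonnodule ratio of large annotated CT collections,
scaled to 600 patches (`mirror_ratio_counts()` scales it to any total).
Exams are assigned round-robin so grouped splits are deterministic.

What the generator does **not** emulate: Hounsfield-calibrated intensity
statistics, scanner noise spectra, 3-D context, anatomical clutter
(ribs, airway walls), or inter-reader annotation variability. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline's
mechanics — extraction, optimization, evaluation — are correct and that
the network can learn separable appearance classes; they say nothing about
clinical performance, which requires the real annotated CT collection.

`generate_annotation_fixture()` closes the loop for the extraction module:
it plants blobs at known centers on synthetic slices, serializes matching
contour/centroid XML, and the tests assert that parsing plus extraction
recovers every planted center within one pixel and routes oversize regions
through the downsample branch.

## Problem sizes used by the checks

The shipped verification runs use deliberately compact cohorts: n = 2000
patches (mirror-ratio imbalance, 40 exams) for the learnability and 3-fold
cross-validation checks, 30-epoch caps, and randomized small shapes for the
oracle comparisons. These sizes were chosen so a complete verification pass
is comfortable on a laptop CPU while still exercising every code path at
realistic minibatch counts; the package itself has no size limits beyond
memory.

## Known limitations

* Training is sample-at-a-time (no batched tensor algebra or GPU path), so
  wall-clock cost grows linearly with cohort size; the full 62k-patch
  collection is feasible but takes hours on one core.
* The FP/exam metric is only as meaningful as the exam ids attached to the
  patches; synthetic exams are bookkeeping units, not physical scans.
* No candidate-detection stage is included: inputs are assumed to be
  candidate ROIs already, and the package classifies, it does not detect.
* Class-imbalance handling (resampling, cost weighting) is intentionally
  absent; the method trains on the natural imbalance.
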