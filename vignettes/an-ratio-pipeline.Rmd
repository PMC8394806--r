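---
title: "Methods: automated A/N-ratio assessment with a keypoint network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated A/N-ratio assessment with a keypoint network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cephan)
```

This vignette is the package's own account of its methods: the measurement
model, the network, the synthetic data, the numerical choices, and the
places where the design was genuinely open and a convention had to be
fixed.

## 1. The measurement model

Fujioka's adenoid–nasopharyngeal ratio is measured on a lateral cephalogram
from four landmarks: basion (Ba), articulare (Ar), the point of maximal
convexity of the adenoid shadow (A′), and the posterior nasal spine (PNS).
The package replaces the classical tangent to the occipital slope with the
chord through Ba and Ar — the tangent line is poorly defined on images with
an unclear occipital slope, while the chord uses only annotated landmarks.
Fitting a tangent is deliberately out of scope.

With ℓ = line(Ba, Ar):

- A = perpendicular distance of A′ to ℓ (adenoid depth),
- F = perpendicular foot of A′ on ℓ,
- N = ‖PNS − F‖ (nasopharyngeal span),
- label = hypertrophic iff A/N > 0.6, **strictly**; a ratio of exactly 0.6
  is normal.

**The definition of N is a documented convention, not an anatomical fact.**
Classical diagrams draw N from the palate edge into the nasopharyngeal
space, but its exact endpoints are not derivable from the four landmarks
alone. We chose the distance from PNS to the foot F because (i) it uses only
the four annotated points, (ii) it measures the nasopharyngeal span toward
the skull-base line through the adenoid's projection, and (iii) it makes A
and N scale together, so the ratio is invariant under rigid motion and
uniform scaling — an invariance the test suite asserts to 1e-9 over 1000
random transforms. Degenerate configurations (Ba = Ar, or PNS coinciding
with F) raise typed conditions (`cephan_error_invalid_geometry`,
`cephan_error_undefined_ratio`) rather than returning sentinels.

Coordinates are continuous, 0-based, origin top-left, x rightward, y
downward; integer coordinates address pixel centres.

## 2. Synthetic cephalograms

Clinical cephalograms cannot ship with the package, so `synth_config()` /
`generate_dataset()` emulate the three image structures the measurement
depends on:

- a bright **clivus ridge** whose endpoints are exactly Ba and Ar;
- a **hard-palate wedge** terminating posteriorly exactly at PNS;
- a **soft adenoid bulge** (a sigmoid-edged disc with a convex rim) whose
  extremal point along the line normal is exactly A′.

The generator works backwards from the label: it samples a severity class
(normal : moderate : severe = 651 : 197 : 53, the cohort mix the pipeline
was designed around), draws the true ratio uniformly in the class range
(normal [0.25, 0.58], moderate [0.62, 0.75], severe [0.75, 0.95]), places
F on the chord and **constructs** A′ = F + (ratio × N) · n̂. Ground truth is
therefore exact by construction; the test suite re-derives every emitted
ratio through `compute_an()` and requires agreement within 0.01. The default
ranges exclude the band (0.58, 0.62) so labels stay unambiguous under small
landmark noise; borderline cases can be re-enabled by widening the ranges.

All landmarks stay at least `margin` pixels (default `image_size/8`, i.e.
32 px at 256) from every border, which is what lets the augmentation
guarantee ROI containment. Blur (σ ≈ 1 px at 256) and additive Gaussian
noise (sd 0.02) are applied last.

What the generator does **not** emulate: cervical vertebrae, dentition,
soft-tissue profile, exposure variation, or the ambiguity of a faint
adenoid contour on a real film. Passing tests therefore demonstrate that
the pipeline's machinery is correct and trainable — not that the network
reaches clinical accuracy on radiographs; the clinical test-set numbers are
not reproducible without the clinical data.

## 3. Augmentation

Each training image yields 17 variants: the original, eight translations
(±10 px axially, (±20, ±20) diagonally, at the 256 px reference scale) and
eight rotations about the image centre. Two conventions had to be fixed:

- **Rotation count and spacing.** Only the total expansion factor (581 →
  9877 images, i.e. ×17) constrains the rotation count: 17 = 1 + 8
  translations + 8 rotations. Angles are evenly spaced over [−20°, 20°]
  excluding 0°: ±5, ±10, ±15, ±20. This is deterministic, symmetric, and
  reproduces the ×17 arithmetic exactly.
- **"20 px diagonal"** is read as (±20, ±20) per axis, not 20 px of
  Euclidean displacement. Both are configurable.

The ROI guard halves a transform's magnitude (at most 10 times,
deterministically) until all landmarks stay in bounds, instead of skipping
the variant — so the count law `n_out = n_in × (1 + 8 + n_rotations)` is
exact, which the suite asserts. Rotation resamples bilinearly with zero
fill; landmarks are transformed with the exact continuous rotation matrix
about ((W−1)/2, (H−1)/2), and translations/rotations preserve the true
ratio to 1e-6, which is also asserted.

## 4. The network

`build_headnet()` assembles: a 7×7/stride-2 stem (64 channels at default),
one 2× max-pool, a 1×1 expansion to `width` (256 default) — so heatmaps
live at input/4, the standard hourglass working resolution — then
`n_stacks` hourglasses of `hourglass_depth` pooling levels built from
bottleneck residual modules (1×1 width→width/2, 3×3, 1×1 back, identity
shortcut), a 1×1 head emitting 4 heatmaps per stack, and 1×1 remap
convolutions between stacks.

Open reconstructions, fixed as package conventions:

- **Stacks = 2** by default: intermediate supervision and the plural
  "hourglass modules" imply a stacked design; two is the minimal stacked
  configuration.
- **Attention placement.** Attention residual modules replace the regular
  residual module at the entry and exit of each hourglass; the hourglass
  interior stays regular. `use_attention = FALSE` gives the plain ablation
  variant. The attention branch gates the bottleneck output with a channel
  gate (global average pool → 1×1 to 16 channels → ReLU → 1×1 back →
  sigmoid) then a spatial gate (channel-mean map → 7×7 conv to 1 channel →
  sigmoid) before the shortcut add. With both gates saturated at 1 the
  module equals the plain residual module — a unit test.

**Integral regression.** Raw head scores (no preliminary activation,
softmax temperature 1) are normalised with a softmax over all heatmap
pixels; the coordinate is the expectation of pixel centres. This is
differentiable, needs no argmax tie-break, and is strictly inside the grid,
so predicted coordinates never need clamping. The suite checks the uniform
grid → exact centre identity, concentration at a peak within 0.01 px, and
agreement with a brute-force double-loop expectation within 1e-5.

**Initialisation** is He fan-in normal for all convolutions, driven by one
seed; builds, forward passes and training runs are bit-reproducible given
the seed. The framework (im2col/col2im in C++, GEMM through BLAS, analytic
backward passes for every module) is validated end to end against central
finite differences at 1e-3 relative tolerance.

## 5. Losses and training

The base loss is the mean absolute difference over the 8 coordinate
components, computed internally in heatmap-grid units (input units divided
by `input_size/heatmap_size` = 4) and reported in input pixels. The two
geometry priors regularise the clivus line rather than duplicating the L1
term: translation = (Da + Db)/2 with Da, Db the distances of predicted Ar
and Ba to the ground-truth Ar–Ba line; rotation = the acute angle (radians,
order-independent) between predicted and true Ar–Ba directions. Both are
exactly zero whenever the predicted line coincides with the true one — the
suite asserts this for arbitrary along-line displacements. λ_rotation =
λ_translation = 0.1 by default, chosen once so the priors stay auxiliary
(about 10% of the base-loss magnitude at convergence on synthetic data);
both are exposed in `loss_config()`. Intermediate supervision sums the loss
over all stacks. At the rotation loss's non-differentiable point (parallel
lines, the minimum) the subgradient 0 is used.

SGD follows the reference recipe: batch 10, momentum 0.9, weight decay
2×10⁻⁵ (weights only, not biases), warm-up to 0.001 and annealing every 5
epochs. Two unstated shapes were fixed: warm-up is **linear over 5 epochs
from a tenth of the base rate**, and annealing is **geometric with factor
0.9** (any positive ramp and any decaying update would satisfy the recipe;
both knobs are in `train_config()`). Non-finite losses abort with a
diagnostic rather than training on. The best checkpoint is selected by
validation A/N error.

## 6. Evaluation

- **Localization**: mean Euclidean error per keypoint plus the
  across-keypoint average, in input pixels.
- **AP/AR**: the matching rule is a design choice because exactly one
  prediction exists per ground-truth keypoint (no detection/confidence
  stage), which makes score-ranked AP degenerate. We use PCK-style
  distance-threshold correctness averaged over thresholds 1..10 px
  (configurable); precision and recall then coincide. F1 is reported as
  the harmonic mean of AP and AR.
- **A/N error**: mean |predicted − true| ratio; degenerate samples are
  excluded with a warning and counted.
- **Diagnostics**: confusion counts with hypertrophic as positive;
  sensitivity, specificity, accuracy, precision, recall, F1, LR+ =
  sens/(1−spec), LR− = (1−sens)/spec. CIs use the **Wilson score** method
  (the CI method had to be chosen; Wilson has good small-sample coverage).
  Note the likelihood-ratio values printed in the reference literature for
  this pipeline (10 and 0.067) are consistent with these standard formulas
  only if sensitivity and specificity exchange roles; the package uses the
  standard formulas and does not tune to match.
- **ROC/AUC**: the predicted ratio is the only continuous score the
  pipeline produces, so it is the ROC score. The AUC equals the
  Mann–Whitney statistic with ties counted ½ (asserted against a
  brute-force all-pairs count to 1e-9); the CI is a stratified bootstrap
  (2000 replicates by default, seeded). pROC provides the curve and
  bootstrap; the Mann–Whitney oracle in the tests is independent of it.

## 7. Problem sizes in the shipped tests

The package's own validation runs at desk scale, chosen once: the
end-to-end training check uses 500 synthetic 64×64 cephalograms (300 train
/ 60 validation / 140 test), ×11 augmentation of the training split
(translations ±3/±5 px and ±10°/±20° rotations — shift magnitudes scale
with the 4× smaller frame), and a reduced network (1 stack, width 64,
hourglass depth 2, 32 stem channels, ~129k parameters) trained 5 epochs
with warm-up to 0.01 over 1 epoch. The higher base rate compensates for
the short schedule; the reference 0.001/200-epoch recipe remains the
default configuration. The augmentation count law is exercised at the full
581 → 9877 arithmetic; the ablation harness runs all four
attention × priors arms at a miniature scale where only the presence and
finiteness of AP/F1/A-N-error fields is asserted — desk-scale sample sizes
cannot resolve differences of a few thousandths between arms, so no
ordering is claimed.

## 8. Known limitations

- The synthetic domain is far easier than radiographs: high-contrast
  structures, no anatomical clutter, no annotation noise. Metrics obtained
  on it characterise the implementation, not clinical performance.
- N's definition is a convention (Section 1); other conventions shift the
  ratio slightly in borderline cases, exactly as replacing the occipital
  tangent by the Ba–Ar chord does.
- The network trains on CPU through BLAS GEMMs; it is sized for method
  validation, not for 2300×2300 clinical throughput.
- `classify_ah()` applies a fixed 0.6 threshold; no calibration analysis is
  provided.
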