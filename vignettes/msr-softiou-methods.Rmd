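---
title: "Methods: the MSR feature-enhancement neck and Soft-IoU scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MSR feature-enhancement neck and Soft-IoU scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trapdetect` implements a minimal two-stage detector for light-trap pest
imagery whose two substantive components are a multi-scale
super-resolution (MSR) feature-enhancement neck and a center-distance-
penalized overlap score (Soft-IoU) used for training-time sample
assignment and test-time duplicate removal. This vignette records the
model, the parameter choices, the numerical decisions, and what the
synthetic test bed does and does not establish.

## The detection pipeline

The pipeline is the classic two-stage arrangement: a backbone produces a
4-level feature pyramid (strides 4–32), the neck enhances it into a
5-level pyramid (strides 4–64, one common channel width), a region
proposal network (RPN) scores anchors and regresses boxes on every
level, the top proposals are pooled by RoIAlign and classified/refined by
a small fully connected head. Cross-entropy is used for both
classifiers; box regression uses L1 in the RPN and SmoothL1 (transition
point 1.0) in the second stage, in keeping with the robustness/stability
trade-off conventional for the two stages. The optimizer is SGD with
momentum 0.9; the full-scale schedule is 12 epochs at learning rate
0.0025 with a ×0.1 step after two-thirds of training, mini-batches of
256 candidates per image at a 1:1 positive:negative ratio in both
stages, and at most 1,000 proposals forwarded to the second stage.

The default backbone is deliberately tiny — a stride-2 stem plus four
stride-2 stages of one 3×3 convolution each, channels (32, 64, 128, 256)
— so that the repository needs no pretrained weights and trains on a
CPU. It honors the same pyramid contract as a ResNet-style extractor
(spatial size `ceil(input / stride)` at every level, strictly doubling
strides), so a stronger backbone can be substituted without touching
anything downstream.

## The MSR neck

**Super-resolution expansion.** The four backbone levels are projected
to the common width (default 256) by 1×1 convolutions. A new stride-2
level is synthesized by a transposed convolution (kernel 4, stride 2,
padding 1 — the unique symmetric choice that exactly doubles the grid)
of the stride-4 lateral; this is the "zoom in" step that recovers
fine-grained texture for very small objects. Top-down fusion then adds
each upper level, bilinearly upsampled, into the level below across the
five finest levels; each fused level passes a 3×3 smoothing convolution;
finally a stride-64 level is appended by stride-2 max pooling (kernel 1)
of the stride-32 output. The result is a 6-level pyramid, strides 2–64.
For an 800×1088 input the six grids are 400×544, 200×272, 100×136,
50×68, 25×34 and 13×17; the test suite pins these sizes exactly.

**Feature full fusion.** Each of the 6 levels is bilinearly resized to
each of the five stride-4..64 target grids; the six same-size maps are
concatenated (6 × 256 = 1536 channels), projected back to 256 by a 1×1
convolution, and added element-wise to the corresponding level. The
residual attachment point is the *post-smoothing* level (the construction
is ambiguous on this point; the residual-on-output reading keeps the
zero-weight limit an exact identity, which the tests exploit). Fusing
into five rather than six outputs drops the stride-2 grid, which exists
to enrich the stride-4 features rather than to host its own heads.

**Feature full weighting.** Each output level X (H×W×C) is re-weighted
as a convex mixture of a positional and a channel term,

    W(X) = alpha * piL(X) * g(X) + (1 - alpha) * piC(X) * X

with, for each position i,

    piL(x_i) = mean over j != i of < theta_L(x_j), phi_L(x_i) >
    piC(X)   = ReLU(theta_C(avg(X))) + ReLU(phi_C(max(X)))

where theta_L, phi_L, g are learnable per-position linear maps (1×1
projections), theta_C, phi_C learnable channel maps on the globally
average- and max-pooled channel vectors, and all maps preserve the
channel count. Three decisions were genuinely open:

* *Normalization of the positional sum.* The pairwise sum has no stated
  normalization; dividing by the number of contributing positions
  (N − 1, i.e. a mean) keeps its magnitude comparable across pyramid
  levels whose position counts differ by three orders of magnitude. A
  config switch (`local_normalization = "sum"`) restores the raw sum.
  A single-position map returns zero (the empty sum).
* *alpha.* No value is stated; the default is the symmetric 0.5, with
  `alpha_learnable = TRUE` making it a trained scalar (clamped to [0, 1]
  after each update) in the spirit of the end-to-end design.
* *The channel gate.* The literal formula is non-negative but unbounded;
  it is used as printed by default, with an optional sigmoid gate
  (`channel_gate = "sigmoid"`) available for long training runs.

The naive positional term is O(N²) in the number of positions. The
implementation uses the algebraic identity
`mean_{j≠i} <θ_j, φ_i> = ((Σ_j θ_j)·φ_i − θ_i·φ_i) / (N−1)`, which is
O(N) and exact; the test suite verifies it against an explicit
double-loop oracle on every map size up to 8×8 and on random larger
maps. The weighting parameters are shared across the five pyramid
levels (they act on the same channel space; per-level copies would
quintuple the parameter count for no clear benefit at this scale).

**Initialization.** Backbone and neck convolutions use He-style
initialization, and the head output layers zero-mean Gaussians with SD
0.01. The weighting block is initialized *near the identity*: g and the
channel maps start small, the channel maps with bias 0.5 so the gate
opens at ≈1, making W(X) ≈ (1 − alpha)·X at the start. Measured at
initialization without this convention, the block inflates the feature
standard deviation roughly sevenfold (the positional term is cubic in
the feature scale), which prevents short training runs from converging
at all; with it, the block's influence is learned rather than imposed.
This mirrors the zero-init convention customary for attention blocks.

## Soft-IoU

For boxes A and B,

    SI(A, B) = beta * (1 - E(A_c, B_c) / max(diag A, diag B)) * IoU(A, B)

clamped two-sidedly into `[(1−c)·IoU, (1+c)·IoU]` with c = 0.1, where
E is the Euclidean distance between centers and diag the box diagonal.
The bracket around the distance penalty is read as ordinary parentheses:
a ceiling would collapse the penalty to the constant 1 for every
overlapping pair (the ratio lies strictly between 0 and 1) and defeat
the purpose of distinguishing equal-IoU predictions. Degenerate boxes
(zero width or height) are rejected rather than allowed to divide by a
zero diagonal; disjoint boxes score exactly 0 for any beta.

Training uses beta = 0.9. A useful closed-form consequence of the clamp:
since `0.9·(1−r) ≤ 0.9` for every center-distance ratio r ≥ 0, the
training-phase score always sits at the clamp floor `0.9·IoU`. The
position suppression therefore acts *relative to the plain-IoU
baseline*: with the positive threshold at 0.5, a candidate needs
IoU ≥ 0.556 rather than 0.5, trimming exactly the borderline boxes. At
test time beta = 1.1 and the penalty is live for ratios up to ≈0.18,
beyond which the floor again binds; duplicate removal (NMS) under this
score suppresses center-shifted near-duplicates less aggressively than
plain IoU at the same threshold. Where the test-phase score acts was an
open choice (NMS, score calibration, or evaluator matching); it is
applied in NMS by default, and the evaluator accepts
`measure = "soft_iou"` to use it in matching as well. Assignment ties
(a candidate equally close to two ground truths) go to the lowest
ground-truth index; each ground truth additionally rescues its
best-scoring candidate as a positive (standard practice, retained here)
provided the overlap is nonzero.

The positive/negative thresholds default to 0.5/0.5 — the Soft-IoU
replaces the *score*, not the threshold convention it is compared
against. Setting `assign_score = "iou"` and `clamp_factor = 0` restores
hard-IoU assignment bit-for-bit (verified on fixtures), which is the
ablation switch.

## The synthetic scene generator

No public light-trap dataset is deposited, so the generator produces the
test bed: textured rotated ellipses ("pests") on a bright, lightly
vignetted board. What it emulates, per the statistics stated for this
kind of imagery:

* mean box area = `relative_area` (default 0.0158) × a reference
  general-object box, itself defined as 38% of the image area (a stated
  constant of the generator; only the ratio semantics matter);
* a between-class mean-area ratio of `scale_spread` (default 32),
  classes geometrically spaced, per-object log-normal jitter
  (mean-corrected, SD 0.25 in log space);
* dense and sparse layouts (4–30 objects per image, overlap-rejected at
  IoU 0.3, 15 placement attempts before skipping with a warning);
* high-similarity class pairs: the second class of each configured pair
  copies the first's size, aspect and color and differs only by a small
  stripe-frequency offset (`similarity_eps`, default 0.3);
* condensation mist as a border-renormalized Gaussian blur plus mild
  contrast reduction; sigma = 0 is exactly the identity and pixel
  variance is non-increasing in sigma.

Ellipse semi-axes are solved so the *rotated tight box* has exactly the
sampled area, and the mask uses 2×2 subpixel coverage, keeping the
realized (pixelated) boxes nearly unbiased; empirical checks in the
suite confirm the realized relative area within ±30% and the class
spread within ±20% of their targets. Scenes are bit-reproducible per
seed. What the generator does **not** emulate: real insect morphology,
occlusion and clutter from debris, illumination failures, motion blur,
or the taxonomy of actual species. Passing tests on these scenes
demonstrates that the pipeline's machinery is correct and trainable, not
that it reaches field accuracy — that claim would require the real
imagery and a pretrained backbone, both outside this package's scope.

## Metrics

Average precision uses 101-point interpolation (precision taken as the
maximum at or above each of 101 evenly spaced recall points) per class
and threshold, with greedy highest-score-first one-to-one matching
within class. `ap_mean` averages thresholds {0.50, 0.75, 0.95} in the
default "literal" mode, or the conventional {0.50, 0.55, …, 0.95} in
"coco" mode — both are provided because reported practice is ambiguous
between them. `m_recall` is the mean over classes of the final recall at
IoU 0.5 (equivalently the maximum recall, since recall is non-decreasing
in the score sweep). Classes with no ground truth anywhere are excluded
from all means. A worked 3-detection/2-ground-truth example with PR
points (1, ½), (½, ½), (⅔, 1) evaluates to AP = 253/303 ≈ 0.835 under
101-point interpolation (the continuous-area value would be 5/6); the
suite checks the implementation against an independently coded evaluator
on this example and on randomized scenes.

## Training at desk scale

The desk profile (`desk_config()`) shrinks widths, not structure:
backbone channels (8, 16, 32, 64), 32-channel neck, 128-unit head,
anchors of scale 2 at ratios {½, 1, 2}, 300 proposals. Three stabilizers
matter for short-schedule training from random initialization and are
defaults:

* linear learning-rate warmup (30 iterations at desk scale) — without
  it, rates above ~0.02 diverge;
* regression losses normalized per positive coordinate rather than per
  sampled batch, keeping the localization gradient strong when positives
  are scarce;
* second-stage training proposals augmented with jittered ground-truth
  copies (12% coordinate noise), so the head learns to refine imperfect
  boxes like the ones it sees at inference.

The end-to-end check trains the full MSR pipeline for 200 iterations on
five fixed 128×128 scenes (K = 3, 6–10 objects, relative area 0.03,
spread 4) and requires AP50 ≥ 0.85 on those scenes; at this miniature
resolution the full-scale defaults (relative area 0.0158, spread 32)
would put the smallest class below 3 px — unresolvable at stride 4 —
so the fixture keeps objects in the 9–22 px regime that full-resolution
inputs occupy. These problem sizes (and the reduced 400×544 canvas and
120-scene sample for the generator statistics) were chosen to keep the
whole suite in the tens of minutes on one CPU.

## Numerical choices and degenerate inputs

* Boxes are continuous, 0-based, corner-convention (x1, y1) top-left;
  area is (x2−x1)(y2−y1) with no +1, matching COCO.
* Bilinear resampling uses half-pixel-center semantics everywhere
  (upsampling, fusion resizes, RoIAlign), so ×2 upsampling and
  arbitrary-size resizes are mutually consistent.
* RoIAlign averages a 2×2 grid of bilinear samples per bin; boxes are
  mapped to levels by `floor(log2(sqrt(area) / finest_scale))`, clamped.
* Box-delta decoding clamps log-scale factors at log(1000/16).
* Global-max pooling breaks ties by first index; NMS ties are resolved
  by detection order within equal scores.
* Gradient checks in the suite compare every kernel's backward pass
  against central finite differences at tolerance 1e-5; the weighting
  oracle equivalence is asserted at 1e-5 (the O(N) rearrangement is
  exact up to floating-point association).
* All randomness — initialization, sampling, scene generation, splits —
  flows from a single integer seed per run; two runs with equal
  configuration and seed are bit-identical.

## Known limitations

* The CPU implementation is single-threaded dense linear algebra; a
  full-size (800×1088, 256-channel) forward pass through the neck takes
  on the order of a minute, so full-scale *training* is out of reach —
  by design, the package demonstrates mechanism, not benchmark accuracy.
* The tiny backbone underfits real texture; the pyramid contract is the
  intended extension point for a pretrained extractor.
* Class-agnostic box regression in the second stage (one box per
  proposal, not per class) is a simplification adequate for the
  single-instance-per-location regime of trap imagery.
* The Soft-IoU training-phase clamp makes the effective training score
  0.9·IoU (see above); configurations with a larger clamp factor would
  let the center penalty act directly and can be explored via
  `soft_iou_config()`.
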