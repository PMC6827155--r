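---
title: "Methods: microaneurysm detection scaffolding on fundus images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microaneurysm detection scaffolding on fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maScreen)
```

## The problem

Microaneurysms (MAs) are the earliest visible lesion of diabetic
retinopathy: small dark-red dots, roughly 15–60 µm across, formed where a
retinal capillary dilates. On a full-resolution fundus photograph they
occupy only a few dozen pixels, sit close to the vessel tree, and are
easily confused with dark vessel pixels and imaging noise. `maScreen`
provides the non-GPU scaffolding of a detection pipeline built around two
ideas:

1. a **feature-fusion neck with attention** that preserves the shallow,
   high-resolution backbone features small lesions live in, and
2. a **spatial-confidence secondary screen** that re-scores candidate
   detections by their distance to the segmented vessel tree.

Everything between those two contributions — image equalization, patch
dataset construction, the training loss, VOC detection metrics, and a
synthetic scene generator providing exact ground truth — is implemented
here as well, so the whole chain is runnable and testable on a laptop
without any external imagery.

## Quality equalization

Fundus photographs vary strongly in exposure and contrast. The
equalization stage works entirely on the **green channel**, where the
contrast between lesions, vessels and background is highest on RGB fundus
images. Two branches run in parallel:

* **CLAHE** (contrast-limited adaptive histogram equalization) enhances
  local contrast. Defaults are `clip_limit = 2` and an `8 × 8` tile grid —
  the de-facto standard operating point in retinal image processing; both
  are configurable. The degenerate single-tile grid falls back to global
  clipped histogram equalization.
* **Otsu thresholding** of the *raw* green channel recovers the circular
  field of view (FOV) as foreground. Computing the ROI from the raw rather
  than the enhanced channel keeps the mask independent of the contrast
  manipulation. The threshold maximizes between-class variance over the
  256-bin histogram; among tied maxima the lowest threshold is taken, and
  the foreground is `pixel > t`.

The enhanced plane is then zeroed outside the ROI. A **quality screen**
precedes all of this: the mean green intensity inside the Otsu foreground
must lie in `[40, 180]` (8-bit scale; below → `reject_dark`, above →
`reject_bright`), and images whose ROI is dominated (> 20%) by large
extreme-intensity connected components are rejected as obscured
(`reject_lesion`). These bounds are engineering defaults — over/under
exposure and "large-area lesion" are not quantified concepts — and are
exposed in `equalization_config()`.

## Patch dataset in Pascal VOC form

Detectors consume fixed-size inputs, so each equalized image is sliced by
a sliding window (`build_patches()`). Window origins form the regular
stride grid plus a final right/bottom-aligned window, so **every pixel is
covered**. Boxes come from 8-connected components of the binary lesion
map; components under 5 px in both extents are dropped (the extreme tail
of the MA size distribution, below any practical detection size). Two
discard rules then apply: a patch must contain at least one lesion box
*fully inside* it, and its nonzero-pixel fraction must reach
`roi_fraction_min` (default 0.1) so that mostly-black blocks from outside
the fundus disc are excluded. Boxes straddling a patch edge are dropped
from that patch rather than clipped — a truncated lesion is corrupt truth
— with a `clip_boxes` flag for the alternative.

Coordinates are 0-based and half-open everywhere inside the package; the
conversion to VOC's 1-based inclusive convention (`xmin = x0 + 1`,
`xmax = x1`) happens exactly once, in `write_voc()`/`read_voc()`, and is
covered by a round-trip identity test. Train/test manifests come from a
seeded shuffle with `round(test_fraction * N)` test ids.

## Attention-based feature fusion

A backbone exposing pyramid levels C2–C5 (strides 4/8/16/32) feeds the
neck. MAs of 10–40 px are essentially invisible at stride 32, which is why
the shallow levels C2–C3 are included at all. Each level is projected by a
1×1 linear map to a common width (256 channels by default), then fused
top-down. At each junction *i* ∈ {4, 3, 2}:

* the running coarse map is **bilinearly upsampled** (half-pixel-centre
  convention, deterministic) to the current level's spatial size;
* **layer fusion** forms `F_i = α₁ f_i + α₂ f′_{i+1}` with learnable
  scalars initialized to 1;
* **channel attention** computes `z = avgpool(F_i)`, passes it through a
  two-layer bottleneck `W₂ · relu(W₁ · z)` with `W₁ ∈ R^{c/8 × c}`,
  `W₂ ∈ R^{c × c/8}`, applies a **softmax over channels**, and scales each
  channel of `F_i` by its weight. The weights are nonnegative and sum to
  one by construction.

The finest fused map (level 2, stride 4) is the neck output. Two points
were genuinely open and resolved as follows. First, the channel-attention
formula as commonly printed repeats the first bottleneck matrix; the only
reading consistent with the declared shapes of `W₁` and `W₂` is
`softmax(W₂ · relu(W₁ · z))`, which is what is implemented. Second,
whether detection heads should consume one fused map or all fused levels
is left open by the design; the single finest map is produced here, and a
caller wanting per-level outputs can invoke the junction operations
directly.

There is no tensor/autodiff framework behind this module: maps are plain
R arrays and the junction's gradients with respect to α₁, α₂, W₁, W₂ are
derived analytically (`junction_gradients()`) — softmax Jacobian, ReLU
gate, pooling averaging — and verified against central finite differences
to a relative error below 1e-4. The backbone itself is a pluggable
contract: `demo_backbone()` supplies shaped, input-dependent pyramids for
tests and demos, and is explicitly **not** a trained network.

## The composite loss

`Loss = L_detection + λ · L_attention`, with λ defaulting to 1 (no value
is prescribed anywhere; it is config-exposed). `L_detection` follows the
two-term region-proposal convention over training triples (anchor B,
target box T, target objectness R): smooth-L1 on the `(dx, dy, dw, dh)`
offset encoding, normalized by the localization count, plus binary
cross-entropy on objectness, normalized by the objectness count. The
specific loss forms are the Faster-R-CNN-family defaults, since the
objective's definition names neither.

`L_attention` compares a predicted score map X with a ground-truth map in
which each annotated box is filled with its confidence score and all
remaining cells with the constant **0.05**; overlapping boxes take the
maximum score (the formula is silent on overlaps; max is the conservative
choice). The comparison is the squared Frobenius norm; whether the printed
form means a sum or a mean of squares is ambiguous, so the sum is the
default with `attention_reduction = "mean"` available. Score maps are
built at the neck's stride (4) to bound memory.

## Spatial-confidence screening

Candidates from any detector are re-scored against the vessel mask:

1. **Distance** (`box_vessel_distance()`): if the candidate box already
   contains a vessel pixel, d = 0; otherwise the box is dilated by 5 px
   per side and d grows by 5 per round, clamping at the image borders.
   The result is exactly `5 · ceil(g / 5)` for the true L∞ box-to-vessel
   gap g, which a brute-force scan confirms in tests.
2. **Spatial confidence**: `C_i = (C_p − d) / C_p`, clamped to [0, 1].
   `C_p = 100 px` by default: ~98% of true MAs lie within 100 px of a
   vessel, so confidence reaches zero exactly where genuine lesions
   become implausible. The formula alone would award `C_i = 1` at d = 0,
   yet detections sitting *on* a vessel are typically dark vessel pixels
   misread as lesions; `on_vessel_zero = TRUE` (default) therefore maps
   d = 0 to `C_i = 0`. Whether true MAs can touch a vessel at distance
   exactly 0 is ambiguous in the underlying statistics, hence the flag
   rather than a hard rule.
3. **Vote**: `S = α · P_class + β · C_i` with α = 0.9, β = 0.1 (the
   documented operating point; a figure caption elsewhere suggests
   β = 0.9, but the running-text value is taken as authoritative — both
   are configurable). A candidate is kept iff `S ≥ threshold`, inclusive.

With the defaults, a true MA carrying `P_class = 0.9` scores at least
0.81 ≥ 0.8 regardless of its distance, while an on-vessel artifact with
`P_class ≤ 0.5` scores at most 0.45 — this is what makes the screening
recovery guarantee checkable without a trained detector.

## Evaluation

VOC2007 protocol throughout: IoU on half-open boxes; greedy matching in
descending score order, each detection claiming its best-IoU unmatched
ground truth (score ties by input order, IoU ties by lowest ground-truth
index), one-to-one; pooled TP/FP/FN across the test set (not per-image
averages); precision, recall, F1 = 2pr/(p+r); and 11-point interpolated
AP — the mean over recalls 0.0, 0.1, …, 1.0 of the maximum precision at
recall ≥ that level, 0 where unreached. Degenerate conventions: precision
and recall are 0 when their denominators vanish, F1 is 0 at p = r = 0.
Greedy matching is not guaranteed optimal; a property test audits it
against exhaustive assignment on small instances and finds agreement in
well over 95% of random cases.

## The synthetic scene generator

`render_scene()` emulates exactly the properties downstream stages
consume, no more:

* a circular FOV disc on a black background with a mild radial
  falloff and Gaussian pixel noise, in fundus-like colours (red ≈ 170,
  green ≈ 115, blue ≈ 45 at centre, 8-bit);
* a **connected vessel tree**: seeded random-walk branches (angle jitter
  σ = 0.18 rad per 2-px step, widths 3–10 px) where each branch starts on
  an existing one; density is kept between 1% and 15% of the FOV;
* **MA lesions** as anti-aliased dark disks at 0.4–0.7 × the local
  background intensity, with diameters drawn from a binned distribution
  (mode 10–20 px at 47.4%) and L∞ box-to-vessel gaps drawn from a binned
  distance distribution (80.7% within 10 px). Placement is by rejection
  sampling against a Chebyshev distance transform of the vessel mask, with
  100 retries per lesion; on failure the lesion count is reduced with a
  warning, never silently. Truth boxes are the tight boxes of the rendered
  lesion pixels, so each box encloses exactly one 8-connected mask
  component and its vessel gap matches the sampled distance within 2 px of
  rasterization slack;
* **illumination variants**: `bright` adds +95 to all channels and `dark`
  scales by 0.22, placing the mean ROI intensity outside the [40, 180]
  acceptance band by construction — these exist to exercise the quality
  screen, not to model real exposure physics.

The generator is a pure function of its `scene_spec()` (including the
seed): identical specs give bit-identical scenes. A `min_distance`
parameter (default 1 px) controls whether lesions may touch vessels.

What it deliberately does **not** model: optic disc, macula, exudates,
hemorrhages, photographic blur, JPEG artifacts, or realistic vessel
branching statistics. Consequently, passing tests on synthetic scenes
demonstrate the *mechanics* of every stage — mask/box consistency,
screening behaviour, metric arithmetic — but say nothing about detection
performance on real fundus photographs, which requires a trained backbone
and real data.

## Problem sizes and numerical choices

Default scenes are 256 × 256 px (tests mostly use 128–160 px with 4–5
lesions per scene); property suites run on 1,000 random rasters for the
Otsu and distance oracles and hundreds of random cases elsewhere. These
sizes were chosen so the full suite and the acceptance script complete in
a couple of minutes on one CPU while still exercising every code path at
scale factors where rasterization effects appear.

Other numerical conventions: Otsu tie-break to the lowest threshold;
bilinear upsampling with `align_corners = FALSE` semantics; softmax
computed with max-subtraction; BCE clamped at 1e-12; the vote threshold
comparison is inclusive (`≥`); sliding windows add edge-aligned extras
rather than padding.

## Limitations

* The detector itself (trained ResNet-101 backbone + region proposal
  network) is out of scope; `detector_oracle()` stands in for it in tests
  and the end-to-end pipeline, and any callable emitting scored boxes can
  be plugged in.
* Patch-count figures reported for real datasets depend on unstated window
  and discard parameters and are treated as configuration, not as
  reproducible targets.
* The greedy matcher and 11-point AP follow VOC2007; COCO-style 101-point
  AP is not implemented.
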