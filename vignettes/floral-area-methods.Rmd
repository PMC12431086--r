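---
title: "Floral area estimation by reference-object photogrammetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floral area estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalpix)
```

## The measurement model

petalpix estimates the projected area of open flowers in a photograph of a
flowering plant. The scene contains one planar reference object of known
physical area; because the flowers and the reference lie (approximately) in
one plane at one camera distance, a single pixel-to-area scale applies to
both, and the floral area follows from a pixel ratio:

$$\mathrm{FloralArea} \;=\; \frac{F_{\mathrm{pixels}}}{R_{\mathrm{pixels}}}\times R_{\mathrm{area}},$$

where $F_{\mathrm{pixels}}$ is the number of segmented flower pixels,
$R_{\mathrm{pixels}}$ the number of segmented reference pixels, and
$R_{\mathrm{area}}$ the known reference area. This is classical planar
(2-D) photogrammetry: the reference calibrates the scale, so the estimate is
invariant to image resolution and camera distance (multiplying both counts
by the same factor cancels). The assumptions worth keeping in mind are:

* **planarity** — flowers displaced towards or away from the camera relative
  to the reference plane are over- or under-scaled; the formula has no depth
  correction;
* **projection** — the quantity measured is projected area, not petal
  surface area;
* **segmentation quality** — every error in either pixel count propagates
  multiplicatively into the estimate; a missing reference is fatal (there is
  no scale), and the pipeline raises a distinct `reference_not_detected`
  error in that case rather than guessing.

The default reference is a 7.6 cm brown cardboard square whose nominal area
is taken as **58 cm²**, the deployment convention this package follows. The
exact square of 7.6 cm is 57.76 cm²; we keep 58 as the published constant
(configurable through `reference_spec()`), which introduces a deliberate,
documented +0.42 % multiplicative offset relative to a geometrically exact
square. Tests that require exact recovery set `area_cm2` to the rendered
reference area instead.

## Pipeline

`run_pipeline()` executes, on one `raster_image`:

1. **Tiling.** The image is split into a 2 × 2 grid of non-overlapping
   rectangles (`make_tiles()`). Tiled ("sliced") inference raises effective
   detection resolution for neural backends. Rectangles are half-open and
   0-based; when a dimension is not divisible by the grid the first tiles
   take the extra pixel (ceil-first rule) — a deterministic convention, since
   any choice here is equivalent as long as the tiles partition the image.
   Tiles do not overlap, which keeps pixel counts exact: each image pixel is
   counted at most once.
2. **Segmentation.** Each tile is passed to two backends — one for flowers,
   one for the reference — satisfying a simple contract: image in, a tibble
   of `(label, confidence, mask)` out. Backends are pluggable; an adapter
   around an external neural instance segmenter only has to satisfy the same
   contract (`segment_with_backend()` validates it and wraps failures with
   the backend id).
3. **Mask merging.** Tile masks are lifted into full-image coordinates
   (`lift_mask()`, a pure translation preserving pixel counts) and pooled.
4. **Confidence filtering.** Detections below the 0.5 confidence threshold
   are dropped (`>=` semantics, `filter_by_confidence()`).
5. **Counting.** Pixels per class are counted as the **union** of that
   class's masks, never the sum (`class_pixel_count()`). Overlapping
   instances of the same class would otherwise double-count pixels and
   inflate the ratio; floral area is a pixel-level quantity, not an
   instance-level one.
6. **Estimation** via the pixel-ratio formula, with all intermediate
   per-tile counts kept in an audit table, and an optional two-colour
   overlay PNG (`save_overlay()`) for visual inspection.

More than one connected reference component in the merged mask triggers a
recorded warning — the protocol expects exactly one reference object — but
the union is still used, leaving the decision to the user.

## The classical colour backend

The deterministic backend (`segment_classical()`) thresholds in HSV (hue in
degrees with wrap-around for reds, saturation and value in $[0,1]$),
optionally applies morphological opening/closing (3 px square brush), labels
8-connected components, and emits each component at or above
`min_component_px` as one detection with confidence 1.0 — the classical
backend has no calibrated score, so the 0.5 cutoff is meaningful only for
probabilistic backends and is exercised with stubs in the tests.

Two defaults deserve justification:

* `min_component_px = 1`: with a positive minimum, a component cut by a tile
  boundary can lose a sub-minimum sliver in one tile, so per-tile
  segmentation would no longer merge to exactly the whole-image result.
  With morphology off and the minimum at 1 the per-pixel classifier is
  strictly tiling-invariant — tiled and untiled runs agree bit for bit.
  Speckle rejection remains available for noisy imagery, at the documented
  cost of exact tiling invariance near boundaries.
* 8-connectivity and the 3 px box brush are the common defaults in
  segmentation practice; they are stated here because component counts (not
  pixel counts) depend on them.

## Statistical evaluation

`regression_metrics()` fits OLS of predicted on measured area and reports
the fit's $R^2$ together with $\mathrm{RMSE}=\sqrt{\tfrac1n\sum(p_i-m_i)^2}$
computed on **identity residuals** (predicted minus measured), not
regression residuals: RMSE measures the estimator's disagreement with ground
truth, while $R^2$ describes the linear relationship. `area_bias()` is the
mean of $p_i - m_i$; positive means over-estimation.

`evaluate_by_category()` groups per-image residuals by flower colour
(T1–T5), petal display (C1–C3) or capture distance (60/80/100 cm) and runs a
one-way ANOVA **on the per-image residuals** — the group bias is the group
mean of those residuals, so this formulation gives the natural degrees of
freedom $(k-1,\,n-k)$ for $n$ images in $k$ groups. Group sizes are always
reported and rows are never silently dropped. `one_way_anova()` decomposes
sums of squares about the grand mean by hand (three lines of arithmetic,
cross-checked against `stats::aov` in the tests) because degenerate inputs
need explicit conventions: all values identical gives $F=0$ with an
`all_identical` flag; zero within-group variance with distinct means gives
$F=\infty$ with an `infinite_f` flag. The p-value is the upper tail of the
F distribution (the regularized incomplete beta function, via `stats::pf`).

Detection quality is evaluated at the mask level: `mask_iou()`, greedy
confidence-ordered one-to-one matching (`match_detections()`, IoU ties to
the lowest truth index — the standard convention, since the matching rule
itself is under-determined by "true positive"), precision/recall, and
all-point precision-envelope AP (`average_precision()`): precision at
recall $r$ is the maximum precision attained at any recall $\ge r$,
integrated over recall — the COCO-style convention, chosen over 11-point
interpolation because it is what modern detection frameworks report.
`mean_ap()` averages AP over IoU thresholds 0.50–0.95 in steps of 0.05, and
over classes with equal weight when labels are present. With zero
predictions, precision is reported as 0 with an explicit
`precision_defined = FALSE` flag rather than NaN, keeping batch summaries
finite.

## The synthetic-scene generator

Real greenhouse imagery cannot ship with a package, so the test bed is a
renderer with exact ground truth. `random_scene_spec()` draws a scene — a
plain grey background, one brown reference square, and 2–5 flowers — and
records **every** random choice in the spec, making `generate_scene()` a
pure function: same spec, bit-identical scene. Masks are rasterized without
anti-aliasing (a pixel belongs to a shape iff its centre does), so
ground-truth pixel counts are integer-exact and the identity
`floral_area = f_pixels / r_pixels × rendered_reference_area` holds
algebraically for every scene.

Design choices, in the package's own words:

* **Distance → scale map.** Capture distance is emulated by the pinhole
  relation `px_per_cm ∝ 1/distance`, with the constant chosen so the 7.6 cm
  reference square rasterizes to exactly 80/60/48 px at 60/80/100 cm
  (`distance_to_px_per_cm()`). The rendered reference is then exactly
  57.76 cm² at every scale; otherwise integer rounding of the square's side
  would make the effective scale itself distance-dependent, and a distance
  ANOVA would detect that quantization artifact rather than the method's
  behaviour.
* **Shape families.** C1 renders as a rosette of petal disks around a
  centre, C2 as a lobed continuous blob
  ($r(\theta)=R\,(0.80+0.18\sin(3\theta+\varphi))$), C3 as a clump of loose
  petal disks. Flower size is drawn as a **target petal area** (9–36 cm²
  per flower) and converted to a bounding radius through each family's mean
  fill fraction (rosette 0.901 and clump 0.300, calibrated once by
  simulation; blob $0.80^2+0.18^2/2=0.6562$ in closed form). This makes the
  three petal-display categories carry comparable areas at the same nominal
  draw, so a category factor is not confounded with total area.
* **Palette.** Flower colours are bright and saturated (value ≥ 0.7):
  T1 mixes red/orange/yellow hues on one plant, T2 pinkish-purple (315°),
  T3 pink (330°), T4 red (0°), T5 purple (275°), each with small stored
  jitter. The reference brown is dark (value 0.45) and the background
  near-achromatic, so the three groups are separable by HSV thresholds
  alone; `default_color_config()` carries the matching ranges.
* **Placement** is uniform at random with bounding-circle separation;
  flowers never overlap each other or the reference. A flower that cannot
  be placed after bounded retries is shrunk and finally dropped so scene
  generation always succeeds on random draws; explicit user specs that do
  not fit raise a placement error.
* **Benchmark structure.** `generate_benchmark()` cycles the 5 × 3 × 3
  factorial of colour × petal × distance through an interleaved enumeration
  (a bijection over the 45 cells) so that even small benchmarks vary every
  factor; 75 scenes cover every cell at least once. Per-scene seeds derive
  from one master seed.

What the generator deliberately does **not** model: perspective and
out-of-plane depth, shadows and illumination gradients, occlusion by
foliage, anti-aliased edges, sensor noise, and complex backgrounds. Passing
the synthetic recovery suite therefore demonstrates that the *pipeline
arithmetic* — tiling, mask merging, counting, scaling, and the evaluation
statistics — is correct, not that any particular segmentation backend will
segment real flowers well; on real imagery accuracy is bounded by the
backend, which is exactly why the backend is a pluggable contract.

## Default problem sizes and numerics

The shipped test-bed sizes are chosen to keep the full suite fast on one
CPU while exercising every code path: 45 × 60 cm canvases (about
474 × 632 px at the 60 cm scale), a 75-scene benchmark for the recovery and
robustness suites, 100 small scenes for the tiling-invariance sweep, and
1000 draws for the ANOVA calibration checks. All tolerances in the tests
are stated next to the property they check: exact (bit-identical) for
tiling, unions and threshold-only segmentation; `1e-9` for sum-of-squares
conservation; 2 % relative for rasterization-limited comparisons (a shape's
pixel count versus its analytic area, and cross-scale estimate spread).

Known limitations: EXIF orientation tags are not read (PNG and TIFF carry
none; JPEGs from rotated cameras should be normalized upstream); images are
2-D RGB only; there is no reference-free or depth-based estimation mode.

## Worked example

```{r example, eval = FALSE}
library(petalpix)

# render a scene and estimate its floral area
spec <- random_scene_spec(seed = 42, color_category = "T1", petal_category = "C1",
                          px_per_cm = distance_to_px_per_cm(60))
scene <- generate_scene(spec)
est <- run_pipeline(scene$image)
est
scene$truth$floral_area_cm2_true

# a 75-scene benchmark, end to end
bench <- generate_benchmark(75, seed = 1)
tbl <- run_benchmark(bench)
glance(regression_metrics(tbl$predicted_cm2, tbl$measured_cm2))
evaluate_by_category(tbl, "distance")
```
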