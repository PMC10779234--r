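---
title: "Grading leaf damage from photographs: models, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading leaf damage from photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(leafgrade)
```

## The measurement problem

A leaf photographed flat on a matte background carries enough information
to quantify its damage: every lesion, hole, or missing bite of tissue
changes either the color field inside the blade or the blade's silhouette.
`leafgrade` turns that observation into a pipeline: segment the blade,
delineate each damaged region, measure areas, normalize by leaf size, and
grade the result into five severity classes. Because no public dataset with
pixel-exact damage ground truth exists for this task, the package carries
its own synthetic-leaf generator whose ground truth is analytic — each
stage of the pipeline is validated against quantities known exactly by
construction rather than against another annotator's opinion.

## Segmentation model

The leaf/background decision is a two-class histogram split. The scalar
channel it runs on matters more than the threshold rule:

* **`bgdist` (default)** — Euclidean RGB distance from the background
  color, estimated as the channel-wise median of the 1-pixel image border.
  This treats black, grey, and brown mats uniformly, requires no tuning per
  mat, and is invariant under intensity negation.
* **`luma`** — Rec. 601 grayscale, the conventional fallback when the
  background estimate is unreliable (e.g. a leaf touching the frame edge).

The threshold maximizes the between-class variance over all 256 split
points (Otsu's criterion). When several consecutive splits tie — the
typical case when the two populations are separated by empty histogram
bins — the midpoint of the tying plateau is used, so the cut falls halfway
between the populations instead of hugging one of them. The foreground side
is chosen as the one whose largest connected component dominates the
central image window; this keeps the decision correct for both light
leaves on dark mats and the reverse.

Morphological cleanup is erosion followed by dilation with a disc kernel
(radius 1 px, 2 + 2 iterations by default): enough to remove sensor salt
and hairline bridges without eroding real notch geometry.

### Contours and the area convention

Region boundaries are traced along the 0.5-level of the zero-padded mask
indicator, i.e. along the "cracks" midway between foreground and
background pixel centers. This convention makes areas honest: a traced
rectangle of k pixels has Shoelace area k − 0.5 (four corner cuts), so
contour areas and pixel counts agree to sub-pixel terms rather than
differing by half the perimeter as pixel-center tracing would.

### Three kinds of damage, one boundary rule

Interior damage is defined as *everything inside the filled blade that is
not healthy tissue*: the union of background-classified pixels (holes, and
lesions whose color happens to resemble the mat) and pixels whose RGB
distance from the healthy-blade color (median over the blade) exceeds
`color_dist` (default 60 of a possible 441). Each connected component is
then labelled a **hole** if background-classified pixels dominate it, else
a **lesion**. Detecting both under a single mask was a deliberate revision:
detecting them separately draws a mat-colored lesion's boundary at the
mat-distance threshold, which sits well inside the true edge and clipped
such lesions by 15–20%.

Lesions ringed by a yellow halo are measured without the halo — the ring is
discolored but present tissue. A pixel is "halo" when
min(R, G) − B > 85. The cut sits at the midpoint between typical lesion
(≈20) and halo (≈140) yellowness deliberately: under edge blur, a lower
cut assigns the blurred lesion/halo transition to the halo and
systematically shrinks every ringed lesion by about a pixel of radius.
Midpoint thresholds give unbiased boundary localization; the same argument
fixes the Otsu plateau rule above.

**Margin notches** (defoliation at the edge) cannot be seen by interior
logic at all. They are recovered as the convex-deficiency of the outline:
the convex hull of the leaf contour minus the filled blade, with
sub-kernel slivers removed by a radius-1 opening and regions below
`min_area_frac` (default 0.0005 of leaf area) dropped. This is the right
tool for bite-shaped losses on a convex blade, and it has a known blind
spot discussed under Limitations.

### The reference area

Per-defect damage is `Dp = area / AT × c × 10` with c = 10, so Dp is a
percentage of the reference area AT. Two conventions are exposed:

* `self` — AT is the image's own blade. Here AT is defined as the
  outer-contour area **plus recovered margin-notch areas**, i.e. an
  estimate of the intact blade. The alternative (contour area alone) would
  inflate Dp for precisely the defect being measured: a leaf that lost 8%
  of its blade to a bite would have that bite scored against the remaining
  92%.
* `dataset` — AT is the mean blade area over a batch (two passes). Under
  this convention a defect larger than the dataset-average blade yields
  Dp > 100; values are kept as computed and only clamped in reports.

Severity bins are half-open `[lower, upper)` with boundaries 1.1, 2.4,
4.1, 6.7 — every positive Dp maps to exactly one of the five classes, with
boundary values belonging to the upper class and ClassFour absorbing the
region just below 6.7.

## The synthetic generator as the instrument of validation

`generate_leaf()` renders a parametric scene: a superellipse blade tapered
to a pointed tip (exponent 2.0–2.5, tip factor 0.15–0.4, semi-axes scaled
to the canvas), colored healthy green with per-pixel jitter, on a black,
grey, or brown mat; damage as interior lesions (reddish-brown, optional
1–2 px yellow halo), holes, and margin notches rendered in the mat color.
Rendering is done without anti-aliasing — a pixel takes a region's color
iff its center is inside the region polygon — so pixel counts match
analytic polygon areas; Gaussian blur (σ = 0.6 px) and additive noise
(σ = 4 intensity units) are applied only after ground truth is recorded.
All randomness flows through one seed; identical specs render
bit-identical PNGs.

Ground-truth areas are analytic: blades and lesions are dense polygons
(720 and 120 vertices) measured by Shoelace; a notch's true area is the
Sutherland–Hodgman intersection of its ellipse with the blade polygon,
which is exact because the blade is kept convex. Notches are generated as
*bites* — ellipse major axis along the inward normal, center pushed half a
semi-axis inside — rather than shallow edge shavings, both because chewed
defoliation looks like that and because a wide shallow shaving loses most
of its area beyond the hull chord, where no silhouette method can see it.

`generate_dataset()` cycles images through the five severity bins
(per-defect Dp drawn uniformly within 0.35–10%), so any n ≥ 5 covers all
classes; roughly 40% of images carry a second small defect. The floor of
0.35% reflects the resolution: below ≈200 px² at 600 × 400, boundary
digitization noise (±3 px) dominates the signal.

What the generator does **not** emulate: venation, specular highlights,
shadows, perspective, soil debris, multiple or overlapping leaves, disease
identity (all damage is "damage"). Tests passing on this suite demonstrate
that the measurement chain is correct, not that the segmenter is robust to
field imagery.

## Dataset building and augmentation

Resizing is anisotropic nearest-neighbor (600 × 400 default); boxes and
areas are rescaled analytically and the annotation flagged `resized`. The
splitter shuffles by seed and allocates ⌊n·f⌋ per split, the first leftover
to train and any further by largest fractional remainder — so 100 → 70/20/10,
10 → 7/2/1, 9 → 7/1/1, and the partition is always disjoint and exhaustive.

Mosaic composition pastes four images into a 2W × 2H canvas around a
random center (uniform in the central 50% window by default), each image
anchored at the center in its quadrant and cropped to fit; boxes are
translated, clipped, and dropped below 10% surviving area, then the canvas
is rescaled. Basic augmentations are restricted to operations with exact
box semantics — flips, right-angle rotation, crop, scale, translate —
plus photometric blur/jitter/noise that leave boxes untouched.
Arbitrary-angle rotation is deliberately excluded: axis-aligned boxes
inflate under rotation with no unambiguous rule.

## Detection evaluation

Matching is greedy per image in descending confidence (ties: larger IoU,
then input order); a detection claims the unmatched ground truth of
highest IoU ≥ α. Greedy can in principle fall one pair short of the
optimal assignment on adversarial overlap patterns; the tests compare it
against exhaustive enumeration on all small fixtures. AP integrates the
monotone precision envelope over recall by all-point summation (the
"continuous" AP of modern detector toolkits); mAP@0.5–0.95 averages α over
0.50–0.95 in 0.05 steps. True negatives are undefined for detectors, so
the accuracy ratio is computed with TN = 0 and labelled as such;
zero-denominator conventions are P = 0, R = 0, F1 = 0. The confusion
matrix matches class-agnostically (cross-class matches are confusion, not
double FP/FN) at α = 0.5 and confidence 0.25 by default, with an extra
background row/column for unmatched detections and ground truths;
column-normalization divides by true-class totals.

## The reference loss

The grid-cell loss is implemented exactly as its printed form: squared
center error and squared size error over responsible predictors, both
weighted λcoord = 5, plus confidence error weighted λcoord on
object-bearing predictors and λnoobj = 0.5 on empty ones. Two departures
from the canonical grid-cell detector are worth flagging: the printed form
uses plain w, h rather than √w, √h, and weights the object-confidence term
by λcoord rather than 1 — the latter is plausibly a typo for a unit
weight. Both printed behaviors are the default; `canonical = TRUE`
switches to square-rooted sizes and unit object weight.

## Numerical choices

* Polygon areas: Shoelace with absolute value; vertex order never matters.
* Point-in-polygon: compiled crossing test (`mgcv::in.out`); rasterization
  restricted to the polygon's bounding box.
* Otsu ties: plateau midpoint (see above).
* Region order: deterministic, by bounding-box top-left corner.
* File formats: VOC boxes are written 1-based inclusive integers; internal
  coordinates are 0-based half-open; YOLO files carry 6-decimal floats, so
  round trips are exact to < 0.5 px (quantization ≈ 3 × 10⁻⁴ px at
  600 px). All format conversions live in one module; nothing else touches
  conventions.
* Degenerate inputs: constant images, empty masks, sub-3-vertex polygons,
  zero reference areas, and non-positive Dp values raise errors naming the
  offending object rather than propagating NaN.

## Problem sizes

The validation suite and the acceptance script use sizes chosen to exercise
every code path at comfortable desk scale: a 50-image 600 × 400 recovery
experiment (the full study condition), 300 × 200 canvases for unit tests,
100 random polygons for the Shoelace oracle, 1000 boxes for round-trip
checks, and a 12-image end-to-end chain with 10 mosaics.

## Known limitations

* **Apex bites.** A notch that removes the pointed leaf tip loses the cap
  between the hull chord and the original tip — information genuinely
  absent from the silhouette. Such regions are underestimated by up to
  ~30%; mid-margin bites recover within a few percent. A blade-shape prior
  would be needed to do better.
* **Sub-resolution regions.** Below ≈0.5% of leaf area, sub-pixel edge
  bias (the color threshold crosses the blurred transition at the 75%
  contrast point, ≈0.4 px inward) approaches 10% of region area;
  recovered areas there are indicative, not precise.
* **Wide shallow edge losses** (shaving rather than biting) are largely
  invisible to the convex-deficiency rule.
* **Scene assumptions.** One leaf per image, near-uniform mat, no overlap
  — field imagery violates all three.
* **Severity near boundaries.** Dp errors of ±0.1–0.3 points flip classes
  for defects lying within that distance of a bin edge; on the synthetic
  suite this caps severity agreement at ~94–99% rather than 100%.
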