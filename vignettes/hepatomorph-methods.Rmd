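---
title: "hepatomorph: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hepatomorph: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatomorph)
```

## The problem

Liver fibrosis staging (F0–F4) ordinarily requires biopsy. On B-mode
ultrasound, two morphological signs of advancing fibrosis are visible in
the sagittal section of the left lobe: irregularity of the dorsal (rear)
capsule and thinning of the lobe. `hepatomorph` quantifies both from a
binary segmentation mask of the lobe: a 16-descriptor particle-analysis
record per subject, a rear-surface roughness call, and the statistics
linking features to stage — Jonckheere–Terpstra (JT) trend tests across
ordered stages and ROC/AUROC with Youden operating points at the ≥F3 and
F4 endpoints. Masks can come from any segmenter (manual, deep-learned, or
the package's classical baseline); the package is agnostic to their source.

## Raster and contour conventions

Every geometric quantity depends on conventions, so they are fixed
package-wide and stated here once:

* Images and masks are matrices `[y + 1, x + 1]`; x rightward, y downward,
  pixel centers at integer 0-based coordinates; intensities in [0, 255].
* `traceContour()` returns the closed polygon through the particle's
  *boundary pixel centers*, counter-clockwise in the y-down frame.
  Consecutive vertices step by 1 (axial) or √2 (diagonal).
* `Area` is the shoelace area of that polygon and `Perimeter` its arc
  length. For a 10×10 pixel square this gives area 81 and perimeter 36
  (side 9): the pixel-center polygon is half a pixel inside the pixel
  footprint everywhere. Against the pixel count (100) the polygon area is
  smaller by O(boundary length); both conventions are self-consistent, and
  the polygon one is used for all contour-derived features.
* The staircase arc length of a digitized circle exceeds the true
  circumference by about 5% (no corner correction is applied — the
  convention is the stated one). Circularity `4πA/P²` of a large raster
  disc therefore lands near 0.89, not 1; the cap at 1 exists because
  raster effects can also push the ratio above 1 for small convex shapes.
  Circularity values are comparable *within* this convention, which is
  what the trend statistics need.
* Foreground connectivity is 8-connected, background holes 4-connected
  (the standard complementary pair). `largestParticle()` keeps the largest
  component, fills holes, and rejects particles under `minSize = 64` px
  (noise specks; configurable).
* `padToSquare()` anchors content top-left and pads with black, so
  annotation coordinates survive padding.

Degenerate inputs error rather than guess: empty masks, single-pixel or
one-dimensional regions (no ellipse), collinear contours (no hull),
contours narrower than 3 px (no front/rear split), polylines shorter than
three smoothing windows (no roughness score).

## Shape descriptors

`Feret` is the maximum pairwise distance over convex-hull vertices;
`MinFeret` the minimum caliper width via rotating calipers (the minimizing
caliper is flush with a hull edge, so only edge normals are scanned).
`FeretAngle` is reported in the y-up frame in [0, 180), matching the
usual "angle against the x-axis" convention; ties between maximal pairs
resolve to the smallest angle, then the smallest x of the first endpoint
(the endpoint with smaller x, then smaller y, reported as
`FeretX`/`FeretY`).

`Major`/`Minor` come from the *equal-area moment ellipse*: orientation and
axis ratio from the second-order central moments of the foreground pixel
centers, axes rescaled so the ellipse area equals the pixel count. This is
the convention of classical particle-analysis tools; the alternative pure
`2√λ` scaling is exact for true ellipses but biased by a constant for
non-elliptical shapes, which matters here because lobe sections are
wedge-like. A consequence worth knowing: `Roundness = 4A/(πMajor²)` equals
`Minor/Major` exactly under this fit, so its two-sided trend p-value
duplicates `AspectRatio`'s. It is still computed and reported — dropping a
listed descriptor silently would be worse than carrying a redundant one.

## Rear-surface roughness

`splitFrontRear()` cuts the contour at its leftmost and rightmost vertices
(ties: topmost); the polyline with greater mean y (deeper in the y-down
frame) is the rear. `roughnessScore()` resamples the polyline at 1-px arc
spacing, smooths x(t) and y(t) with a `smoothWindow = 31` px moving
average, and returns the RMS point-to-smoothed-point residual, excluding
half a window at each end where the truncated average hugs the curve. The
moving average passes undulations much longer than the window and removes
those much shorter, so the statistic responds to capsule irregularity at
the 10–40 px scale while ignoring the lobe's overall curvature. For a
sinusoid of amplitude A and wavelength well under the window (and gentle
slope) the score approaches A/√2, which anchors its scale.

The smooth/rough call compares the score to a threshold calibrated by
maximizing balanced accuracy on a labeled set — in the pipeline, a
separate synthetic cohort. This deterministic scorer stands where a
CNN classifier would sit in a clinical deployment; the evaluation path
(`evaluateClassifier()`, per-class and overall accuracy percentages)
accepts calls from any scorer, so a learned model can be plugged in
without touching the rest. `focalLoss()` (natural log, default γ = 2, the
canonical setting of the loss it implements) is provided for training such
a classifier under class imbalance; γ = 0 recovers cross-entropy.
Augmentation (`affineAugment()`) is restricted to ±10° rotation and ±10%
per-axis translation with no scaling: pose perturbations that leave shape
cues intact. The translation bound is interpreted per axis (the total
bound is not stated anywhere authoritative; per-axis is the common
reading and is what the exactness test pins down).

## Segmentation metrics and baseline segmenter

`segMetrics()` computes TP/FP/FN pixel counts and IoU, F and Dice loss
from the raw counts — never batch-averaged, so the identity
`F = 2·IoU/(1 + IoU)` holds to machine precision and `DiceLoss = 1 − F`
by construction. Aggregates report both per-image means and pooled-count
metrics, which differ when image difficulty varies; published aggregate
Dice figures that disagree with 1 − F typically come from some batch
averaging, which is why both are written out.

`baselineSegmenter()` estimates a global Otsu threshold on a box-smoothed
copy (stabilizing the histogram against speckle) but applies it to the raw
image, then closes with a 5-px disc and keeps the largest filled particle.
Applying the threshold to the raw image keeps noise-free two-level images
exactly recoverable; the morphology absorbs pixelwise speckle errors.

## Trend and diagnostic statistics

The JT statistic sums Mann–Whitney counts over ordered group pairs, ties
counting ½. Inference:

* **exact**: full enumeration of distinct group-label arrangements when
  their number is ≤ 20 000 (e.g. 90 for three groups of two);
* **monte_carlo**: seeded permutation (default 10⁵) on request;
* **normal**: tie-corrected normal approximation otherwise.

Two-sided p-values are twice the smaller tail, capped at 1; two-sided is
the default (the common software default for this test). No continuity
correction is applied. No multiplicity adjustment is made across the 16
features — raw p-values are reported, and callers can `p.adjust` if their
question requires it.

`rocAuc()` computes AUROC by pairwise concordance (rank form), so it is
invariant under strictly monotone transforms. With `orientation = "auto"`
a feature whose lower values indicate disease (as left-lobe thickness
does) is flipped and flagged `low_positive`. The operating point maximizes
the Youden index; how published sensitivity/specificity pairs were chosen
is generally not recoverable, so Youden is adopted as the stated,
reproducible rule. `confusionFromRates()` inverts printed
sensitivity/specificity against known class sizes (warning when a rate is
not integer-consistent with the sizes), and `f1FromConfusion()` completes
the reconstruction of F-1 scores from published operating points.

## The synthetic cohort: what it emulates, and what it does not

The generator's defaults encode the study conditions the package is
tested under: 43 subjects with stage counts 5/11/13/11/3, a baseline
semi-minor axis of 90 px (SD 9) on a 512×512 canvas shrinking by 10% of
baseline per stage step, and rough-rear prevalence rising
0.05/0.15/0.25/0.40/0.60 across F0–F4 (≈27% overall, matching the
reported rough:smooth imbalance; the stage profile of prevalence is not
published anywhere, so this rising profile is a modeling choice, exposed
in the config). The silhouette is a superellipse `|x/a|^p + |y/b|^p = 1`
with bluntness p = 2.5 and a 10% linear caudal taper — a two-parameter
control of margin bluntness and wedge profile. Roughness is a sum of
random-phase sinusoids (15–50 cycles per boundary, i.e. nodularity at
the 15–45 px scale along the rear arc), windowed to the rear half and
applied radially, so perturbed shapes remain simple polygons. Rendering
adds mean-1 Rayleigh multiplicative speckle (lightly correlated),
a darker background, and a bright 2-px capsule line.

What passing tests on this cohort show: the descriptor pipeline measures
what the generator injected (axis recovery within stated tolerances,
monotone roughness response, trend detection at the injected effect size,
nominal type-I error under the null). What they do not show: performance
on clinical images — real capsules have acoustic shadowing, partial
dorsal obscuration by stomach gas, operator-dependent section choice, and
annotation ambiguity, none of which the phantom models. The synthetic
results validate the measurement chain, not the clinical claim.

Problem sizes used in the checks are chosen for a desk-scale run: the
type-I calibration (1000 null cohorts) runs at the generator's sampling
layer (truth parameters, no rasterization) because under the null config
(zero shrink, constant roughness prevalence) stage labels are
exchangeable, so the measured test statistic has the identical null law;
trend *recovery* is verified on fully rasterized cohorts.

## Reproducibility

Every stochastic step takes a seed; `generateCohort()` is a pure function
of its config, and truth parameters are drawn before any rendering so
`render = "none" / "mask" / "full"` agree on ground truth. The pipeline
fans one master seed out via `childSeed()` (a stable label hash), records
all child seeds in `manifest.json`, and writes byte-identical outputs on
rerun.

## Known limitations

* Single-particle analysis only; multi-lobe or multi-organ masks must be
  reduced upstream.
* The roughness statistic is scale-bound by its window: irregularity at
  wavelengths near or above `smoothWindow` is attenuated
  (and partially absorbed into the smoothed curve), so the calibrated
  threshold is only valid for the resolution it was calibrated at.
* Perimeter (and hence Circularity) carries the ~5% staircase bias of the
  stated convention; comparisons are valid within the package, not across
  tools using corner-corrected perimeters.
* The baseline segmenter assumes a bright lobe on darker surround with a
  capsule line; it is a stand-in for, not a competitor to, learned
  segmenters.
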