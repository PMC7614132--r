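---
title: "Quantifying organoid morphology and marker signal with organoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organoid morphology and marker signal with organoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoquant)
```

## The measurement problem

Small-intestinal organoids grow as a heterogeneous population: immature,
round, thin-walled **spheroids** of undifferentiated proliferating cells,
and mature **budding** organoids whose crypt-like protrusions house stem
and Paneth cells. Cytokine treatments shift this balance, change organoid
size, and darken dying organoids — brightfield gray value is therefore a
continuous viability readout ("higher value is whiter"), not a class.
Downstream, confocal stains ask per-object questions: how many DCLK1+ tuft
cells does each organoid carry, what fraction of pixels in a region is
positive for a marker, how strong is a signal near a reference structure
compared to background?

organoquant implements this measurement chain as composable stages:

1. **project** a z-stack to one plane,
2. **segment** organoid objects from background,
3. **extract** per-object area, mean gray and shape features,
4. **classify** each object spheroid/budding (CNN or shape-feature rule),
5. optionally **correct** calls manually via a review sheet,
6. **detect and count** marker puncta per organoid,
7. **summarise** per treatment and compare groups.

Every stage is validated against a synthetic scene generator that emits
complete ground truth, so the package's accuracy claims are reproducible
computations, not assertions.

## Projection and segmentation

Brightfield organoids are darker than the background, so the default
brightfield projection is the pixelwise **minimum** across z (the darkest
plane keeps the object) while confocal channels default to the **maximum**.
Only these pixelwise reductions (min/max/mean) are offered; they carry the
stack's calibration onto the projected plane.

Segmentation is classical and deterministic: Gaussian smoothing
(`smoothing_sigma`, default 2 px), a global threshold, hole filling, a
minimum-area filter (`min_area_um2`, default 200 µm²), optional
distance-transform watershed splitting of touching objects, an optional
border-object drop, and label compaction.

**Why the default threshold is not Otsu.** Otsu's rule minimises
within-class intensity variance, which implicitly assumes the two classes
have comparable spreads. An organoid field violates this: the background is
one tight mode, but object interiors span a wide range (roughly 0.2–0.6 of
the dynamic range, since dying organoids darken progressively). On such
fields a minimum-variance threshold can land *inside* the object class and
silently discard the palest organoids. The default mode `"background"`
instead anchors the threshold to the background mode: threshold =
median − k·MAD of the smoothed image (k = `background_k`, default 4),
on the dark-objects polarity. Otsu (`"otsu"`) and fixed values (`"fixed"`)
remain available for users whose material matches their assumptions.

A second consequence of variable interior gray is that no *single* global
threshold cuts every object's blurred edge ramp at its half height: a
global cut systematically dilates pale objects and erodes dark ones. With
`refine_boundaries` (default on) each object is re-thresholded locally at
the midpoint between the background level and that object's median interior
intensity, keeping the connected component that overlaps the initial
object. On the built-in benchmark this raises mean intersection-over-union
against ground-truth masks from ≈0.85 to ≈0.98 without changing
detection precision or recall (both 1.0 over 20 scenes of 5–20 objects).

Watershed seeds are the maxima of the interior distance map within
`watershed_tolerance`; ties are resolved by the fixed scan order of the
underlying implementation, so splitting is deterministic.

## Morphometrics

`extract_features()` reports, per object: `area_um2` (pixel count ×
pixel size²), `mean_gray` on the native bit-depth scale, and the shape
features used by the fallback classifier — solidity (object area / convex
hull area, hull taken over pixel corners so small objects are not
degenerate), circularity (4πA/P², capped at 1), and equivalent diameter.
Centroids are exported 0-based (row, col), row-major, the single coordinate
convention used across all tables.

Physical units depend entirely on user-supplied calibration: plain TIFF
files written by the package carry pixel size in a JSON sidecar, and
foreign TIFFs without one default to 1 µm/px with a warning rather than
silently conflating µm² with pixel².

## Classification

The class set is closed to `{spheroid, budding}`; darkness is a continuous
annotation, never a third class. Two interchangeable models share one
interface:

* **CNN** (default): three convolution/ReLU/max-pool blocks
  (8, 16, 32 filters; 5×5 then 3×3 kernels) and a 32-unit dense head on
  single-channel crops, trained with Adam at learning rate 1e-3 for 6
  epochs. It is implemented directly on BLAS matrix products (im2col), all
  randomness drawn from R's RNG, so a fixed seed reproduces weights exactly
  on a fixed platform. Crops default to **64×64 px**: the network trains on
  1,000 crops in about a minute on one CPU core at this size, and held-out
  accuracy on the synthetic benchmark is indistinguishable from larger
  crops, so the smaller side is the default.
* **Shape-feature fallback**: a logistic rule on crop solidity,
  circularity and extent, fit with `stats::glm`. It is deterministic,
  interpretable, and serves as an independent cross-check of the CNN — the
  two routes agree on ≥80% of the benchmark by construction of the tests.

Crops are tight bounding boxes with a 15% margin, masked to the object
(background pixels set to `pad_value`), padded square and resampled.
Objects below `min_crop_pixels` (default 50) are flagged unclassifiable and
are *never* assigned a class. Predictions whose winning probability is
within `decision_margin` (default 0.1) of 0.5 are labelled `unclassified`
and routed to review — the package does not guess on calls a human would
double-check.

The manual-correction cycle mirrors practice: `export_review_sheet()`
writes one CSV row per organoid (uncertain calls sorted first),
`apply_corrections()` applies the reviewer's `corrected_class` and `reject`
flags idempotently, retaining the pre-correction label in provenance.
Rejected organoids are excluded from every downstream count, summary and
comparison. `concordance()` quantifies automatic-vs-corrected agreement
with a confusion table whose marginals equal the class counts.

## Marker quantification

**Positive pixels.** "Positive" is strictly `intensity > threshold`, with
per-marker thresholds in the config; there is no published threshold to
inherit, so fixed values (reproducible) and Otsu (automatic) are both
supported. `roi_positive_ratio()` covers the two ratio patterns used on
stained tissue — one channel across two ROIs (e.g. crypt/villus) and two
channels in one ROI (e.g. pSMAD2+/DAPI+ pixels) — and flags a zero
denominator as an undefined result rather than returning infinity.

**Spot detection.** Tuft-cell puncta are detected on the (projected)
marker channel by multi-scale scale-normalised Laplacian-of-Gaussian
filtering over `sigma_min`–`sigma_max` (defaults 1.5–4 px, 4 log-spaced
scales), spatial 3×3 local maxima that also dominate adjacent scales,
an intensity criterion, and greedy non-maximum suppression at
`min_separation` (default 5 px; strongest response first, ties by row then
column — deterministic). The default intensity criterion keeps peaks above
median + `snr_factor`·MAD of the lightly smoothed channel with
`snr_factor = 6`: over a ~0.26-megapixel field the expected extreme of
smoothed background noise is ≈4.5 robust SDs, so a factor of 4 would admit
false positives *by construction* while genuine puncta at the design
signal-to-noise of ≥5 sit tens of SDs above background. Each detection is
assigned the mask label under its centroid; background detections are
dropped (and reported, so assigned + dropped = total always holds) or
reassigned within an optional capture radius.

**Counts and rules.** `fraction_high_tuft()` implements the "more than
*n* tuft cells" readout as a strict inequality with a configurable cutoff
(default 8). Curated counting applies a detection-level review CSV
(add/remove rows) before counting, mirroring the automatic-vs-curated
duality of real workflows. `aggregate_by_subject()` enforces the
"mean of at least `min_rois` ROIs per subject" rule (default 5), excluding
and reporting subjects below the minimum. `proximity_signal_ratio()`
realises "signal in the immediate vicinity of a reference" as morphological
dilation of the reference mask by a radius in µm (default 5 µm), with
manually drawn masks accepted as-is at radius 0.

## Group comparisons

`compare_groups()` offers unpaired Welch (default), pooled-variance
Student, and paired two-tailed t-tests via `stats::t.test`. Welch is the
safer unpaired default when only "unpaired two-tailed t-test" is specified;
the variant used is recorded in the result. Each comparison must declare
its unit of replication (organoid vs mouse), because the honest unit varies
by experiment design. Two groups with zero variance and equal means return
statistic 0 and p = 1 explicitly. No multiple-testing correction is applied
by default (per-panel tests); `stats::p.adjust` composes trivially where
wanted.

## The synthetic generator: what it does and does not emulate

`generate_brightfield_scene()` draws fields of 5–50 organoids: spheroids as
smooth ellipses (solidity ≈ 0.96) and budding organoids as a central body
with 2–6 overlapping lobe disks (solidity ≈ 0.86), so lobe geometry — not
texture — carries the class signal that both classifier routes can learn.
Intensity layout: background at 0.8 of the dynamic range, interiors
0.2–0.6 (objects darker than background; darker = dying), a ±4%
multiplicative shading field, additive Gaussian noise at 2% of range.
`degrade_scene()` re-renders selected objects with interiors multiplied by
a darkening factor before noise, updating the ground truth, to exercise the
gray-value metrics. `generate_confocal_scene()` adds a dense-nuclei channel
and a marker channel with Gaussian puncta (σ = 2 px) at ground-truth
positions; per-organoid counts follow a per-class law, defaulting to
Poisson means of 5 (budding) and 0.5 (spheroid) — tuft signal concentrated
in budding organoids — truncated at 12.

Confocal organoids default to larger bodies (radius 20–32 px) and 640×640
scenes: at the default 7 px spot separation, random sequential packing jams
near 14 spots in the smallest such organoid, so the 12-spot maximum always
fits. Spot placement is pool-based dart throwing (candidates within the
separation of an accepted spot leave the pool), which reaches that packing
limit reliably; a request beyond capacity raises an explicit placement
error rather than quietly under-placing. Scenes are pure functions of
(parameters, seed).

The generator does **not** emulate: optics (PSF, depth attenuation),
texture inside organoids, overlapping or out-of-focus objects, uneven
illumination beyond the smooth shading field, or 3-D structure (z-stacks
are replicated planes with independent noise, via `scene_zstack()`).
Passing the benchmarks therefore demonstrates that the *algorithms and
bookkeeping* are correct under controlled conditions; it does not certify
accuracy on real micrographs, where segmentation and classification
parameters must be tuned and spot-checked through the review cycle.

## Benchmark suites and problem sizes

The test suite and `scripts/acceptance.R` recompute, from freshly generated
scenes: segmentation precision/recall at IoU 0.5 and mean matched IoU over
20 brightfield scenes (512×512, 5–20 objects); CNN and fallback held-out
accuracy (1,000 training / 200 test crops); exact-count fraction and
centroid error for tuft spots over 20 confocal scenes (120 organoids,
counts 0–12); and the exact statistic contracts (strict thresholds,
self-ratios, the closed-form t-test). These sizes give stable estimates in
a couple of minutes on one CPU core; all scale with their parameters.

## Numerical and degenerate-input choices

* Intensities stay on the native integer scale end to end; bit depth is
  recorded and files round-trip losslessly (16-bit label masks cap at
  65,535 objects with an explicit error).
* Empty inputs are errors, not zeros: an empty count vector has no defined
  "percentage above cutoff", an empty ROI has no positive fraction.
* Undefined ratios (zero denominator) are flagged, never silent `Inf`.
* All tie-breaks (watershed seeds, NMS order, pooling argmax) are fixed by
  deterministic scan order; reruns with one config and seed are
  bit-identical, and the pipeline writes a manifest (package version, seed,
  parameters, stages) sufficient to reproduce a run.

## Known limitations

* Segmentation is 2-D on projections; organoids overlapping in z merge.
* The CNN is trained per project (no shipped weights); on real data it
  needs labelled crops, typically bootstrapped from the review cycle.
* Blob counting approximates cell counting; touching nuclei at the
  detection scale under-count, which is why the curated policy exists.
* The shape fallback relies on crop masks; heavily fragmented masks weaken
  its features.
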