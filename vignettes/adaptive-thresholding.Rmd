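---
title: "Adaptive color thresholding for fruit detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive color thresholding for fruit detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitseg)
```

## The detection model

`fruitseg` segments fruit pixels from background in RGB images by
thresholding in a three-dimensional color space, with thresholds that
adapt to local illumination. The model a call to `fruit_fit()` returns
consists of:

* a **split configuration** — the stop-splitting standard deviation
  *STD*, a minimum region side, the light cutoffs *T1 < T2* and an
  overexposure cutoff;
* three **anchor light levels** (low / medium / high), the mean observed
  gray level of each light group's training regions;
* a **3 × 3 threshold table** (light group × color dimension);
* three **classification directions** (is fruit above or below the
  cutoff in each dimension);
* one of seven **mask combinations** (a single dimension or an
  intersection of two or three).

Detection splits the image quadtree-fashion until each region's grayscale
standard deviation is at most *STD* (or the region is too small to split),
computes each region's mean gray level, linearly interpolates the
threshold table between the two bracketing anchors, binarizes each color
dimension, intersects per the chosen combination, and finally cleans the
mask by morphological opening with an 11 × 11 square element followed by
closing with a 5 × 5 square. Regions brighter than the overexposure
cutoff emit background: they carry no usable color contrast, and emitting
background keeps every output pixel defined.

The selection criterion throughout is the balance
\(F = 2\,\mathrm{TPR}\,(1-\mathrm{FPR}) / (\mathrm{TPR} + 1 - \mathrm{FPR})\)
of the pixel-level hit rate against the complement of the false-alarm
rate, defined as 0 in the degenerate corner TPR = 0, FPR = 1. An
`objective_weight` argument replaces it with the linear score
\(w\,\mathrm{TPR} + (1-w)(1-\mathrm{FPR})\) for deployments that need to
shift the hit/false-alarm trade-off (e.g. approach versus grasp phases of
a harvesting robot).

## Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| `std_stop` | gray levels (0–255) | tuned by grid search | smaller values split more aggressively; beyond the point where regions are illumination-homogeneous, further splitting risks single-class regions |
| `min_side` | px | 16 | a region below ~16 px per side rarely contains both fruit and background, so no threshold can be learned from it |
| `t1`, `t2` | gray levels | 15th / 85th percentiles of sampled light levels | leaves 15% of sub-images low, 70% medium, 15% high |
| `t_over` | gray levels | 250 | regions brighter than this are effectively washed out |
| `n_levels` | thresholds per sweep | 256 | matches 8-bit source precision |
| `tile_fraction` | proportion | 0.01 | light levels are sampled on tiles of 1% of the image's pixels |
| `sample_fraction`, `repeats` | — | 0.30, 5 | subsample size and repetitions of the *STD* grid search |
| `bg_majority` | proportion | 0.70 | the direction heuristic assumes at least 70% of pixels are background |

Directions are learned by probing each dimension at the midpoint of its
channel range: if fewer than 70% of the pooled training pixels fall at or
below the probe, fruit is taken to lie *below* the cutoff instead of
above. The probe threshold is coarse by design — the heuristic only needs
to identify which side of the distribution is background.

## Numerical choices

* **Interpolation.** Thresholds at light level \(x\) between anchors
  \(L_i \le x \le L_{i+1}\) are
  \(T = [T_i (L_{i+1} - x) + T_{i+1} (x - L_i)] / (L_{i+1} - L_i)\):
  exact at the anchors and continuous in between. Levels outside the
  anchor span clamp to the nearest anchor. A `interp = "reversed"`
  option swaps the two weights — an alternative reading of the rule that
  agrees with the standard one only at the bracket midpoint — and exists
  for comparison, not as the default, because reversed weights are
  discontinuous at the anchors.
* **Threshold tie-breaking.** For separable classes, every candidate
  threshold in the gap between the class supports ties at F = 1. The
  sweep returns the *center* of the tied plateau. An endpoint rule
  (e.g. always the lowest tied candidate) places the cutoff at the edge
  of the observed background support, where a test image whose
  background sits marginally higher flips wholesale; the plateau center
  maximizes the margin to both classes, like the midpoint split of a
  decision stump.
* **Zero NDI denominators** (e.g. R + G = 0) map to 0, the symmetric
  "no difference" value, keeping the channel inside [−1, 1].
* **Percentiles** interpolate linearly between order statistics
  (`quantile` type 7).
* **Group fallbacks.** A light group observed without both classes (say,
  no fruit ever seen in low light) borrows the nearest populated group's
  thresholds, with a warning; its anchor falls back to the midpoint of
  its light band so anchors stay strictly increasing.
* **Boundary cases of the light grouping**: levels exactly at *T1* or
  *T2* belong to the upper group — a deterministic, measure-zero choice.
* **Stop-value grid search** evaluates every candidate on the *same*
  seeded folds (common random numbers), so candidates yielding identical
  models — e.g. stop values so large the image never splits — score
  identically, and ties resolve toward the larger (cheaper) candidate.
* **HSI variant.** "HSI" is often conflated with hexcone HSV. The
  classical intensity model (I = channel mean, S = 1 − min/I) is the
  default; `variant = "hsv"` is exposed. All channels are scaled to
  [0, 1] so one sweep grid serves every space.
* Grayscale is ITU-R BT.601 luminance; CIELAB is sRGB under D65, the
  convention of consumer cameras.

## Design choices where the design was open

* **Split geometry** is a midpoint quadtree: the simplest top-down scheme
  that produces variably sized rectangles; odd sides put the extra pixel
  in the second half.
* **Pooled learning.** Thresholds are learned from pixels pooled per
  (group, dimension) rather than per sub-image ROC curves: pooling is
  robust to tiny regions that contain no fruit.
* **Anchors are observed group means**, not fixed reference levels, since
  the cutoffs *T1*/*T2* are themselves tuned; anchors must sit inside the
  tuned groups.
* **The deployed combination is selected on training data** by mean
  F-score, ties toward fewer intersected dimensions; the per-combination
  training scores are kept in the model (`training$combination_scores`)
  for transparency.
* **Morphology is applied once, to the final combined mask** — cleanup of
  intermediate masks would interfere with the intersection logic.
* **Cross-validation re-tunes the light cutoffs and directions inside
  every repeat on the training fold only**, avoiding leakage from test
  images into tuning; the stop value is held fixed across repeats (its
  own tuning is already an internal cross-validation, and nesting the
  two multiplies cost without changing the comparison being made).
* **Noise model.** Sensitivity analyses read "n% noise" as zero-mean
  Gaussian noise with standard deviation n% of full scale (255) per
  channel, added to test images only by default.

## What the synthetic scenes emulate — and what they do not

`generate_scene()` builds labeled scenes of elliptical "fruit" blobs
(per-fruit jittered color, default red on green foliage) with pixel-exact
ground truth, under a multiplicative illumination field — a smooth ramp
or piecewise-constant dark/medium/bright bands — optional additive
offset, background brightness texture, and Gaussian pixel noise. Default
fruit semi-axes (18–26 px) make fruits span roughly 40–50 px, large
relative to the 11 × 11 cleanup element, as real fruit are at typical
camera resolutions; a separation margin keeps fruits distinct connected
components.

Multiplicative gain is exactly the condition NDI normalizes away, so
red-on-green scenes in NDI space are separable by construction and the
pipeline should — and does — reach F = 1 before morphology; this
validates the machinery, not field performance. The step-banded scenes
create the opposite condition: in RGB space the class supports of
different bands overlap (dark fruit is darker than bright background), so
one global threshold must sacrifice roughly a band's worth of pixels
while per-band thresholds separate cleanly — the core argument for
regional adaptation, testable exactly. The generator does **not** model
occlusion, leaves, specular highlights, fruit texture, or the
green-on-green case where color alone cannot separate the classes; a
passing suite therefore says nothing about such scenes, and real
deployments should expect the gap between these idealized conditions and
field data to dominate error.

Test and evaluation problem sizes are deliberately desk-scale: scenes of
160 × 224 pixels and datasets of 8–20 images, with 5-fold repeated 70/30
splits — about the size of the smaller orchard databases this family of
detectors is designed for, and enough for every learned quantity to be
exercised without long runtimes.

## Known limitations

* Color thresholding only: no texture or shape features, so crops that
  match their background color need additional features.
* The direction heuristic fails if fruit covers more than ~30% of the
  training pixels in a dimension.
* Thresholds are interpolated but learned from hard group assignments; a
  light distribution with no clear structure can place group boundaries
  inside clusters, blurring the pooled buckets (the percentile rule
  inherits this from the data).
* The overexposure cutoff is exposed but not tuned; truly washed-out
  regions carry no signal for tuning it.
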