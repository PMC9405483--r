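---
title: "Counting cells and debris in confocal hippocampal z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cells and debris in confocal hippocampal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippocount)
```

## The quantification problem

Triple immunofluorescent staining of rodent hippocampus labels neurons
(NeuN), astrocytes (GFAP) and microglia (IBA1) in three channels. The
quantities of interest per region of interest (ROI) are per-class cell
densities (cells/mm²), the thickness of the stratum pyramidale (the packed
pyramidal-cell band, a neurodegeneration index), and the density of
*neuronal debris* — sub-somatic NeuN-positive fragments lodged against
astrocyte branches, a marker of neuronal damage and clearance.

`hippocount` implements the full counting pipeline for calibrated
three-channel z-stacks, a synthetic-stack generator that provides ground
truth for testing it, Bland–Altman agreement statistics for validating
algorithmic counts against manual ones, and the small defined statistics
that accompany such a study (brain-to-plasma concentration ratios, the
novel-object discrimination index, Racine-scale kindling bookkeeping).

## The detection model

Each z layer of the counted channel passes through four stages:

1. **Gaussian smoothing** (`preprocess_layer()`), σ in µm converted to
   pixels per axis, to suppress shot-like noise.
2. **Adaptive thresholding** (`threshold_layer()`): a pixel is foreground
   iff it exceeds the mean of its surrounding block (default 30 µm) plus a
   constant offset. Local-mean referencing makes the binarization invariant
   to smooth background gradients and to adding a constant to the whole
   image — properties the test suite asserts.
3. **Morphological refinement** (`refine_mask()`): opening then closing
   with a small disc. This alternating filter is idempotent; re-application
   changes nothing.
4. **Blob extraction** (`extract_blobs()`): 8-connected components are
   measured — area as pixel count × physical pixel area, and the *Feret
   (longest) diagonal* as the maximum pairwise distance over the
   boundary-pixel corner points, with per-axis µm scaling. Blobs touching
   the raster border are dropped by default, mirroring the exclusion of
   edge photon scatter from analysis.

Blobs in consecutive layers are then **linked** (`link_layers()`) when
their pixel overlap is at least 60% of the smaller blob's area; ties are
resolved greedily by largest overlap, then nearest centroids, so every blob
joins at most one track. A track **is a cell** (`classify_cells()`) iff it
spans at least two consecutive layers and its maximum Feret diagonal
*strictly exceeds* 6.5 µm. Cells are counted once per track, never per
layer.

**Neuronal debris** (`detect_debris()`): a non-cell track whose Feret
diagonal lies in the closed interval [2.5, 6.5] µm is a candidate; its
*encirclement* is the fraction of its surrounding ring (the blob dilated by
1 µm, blob subtracted) covered by the astrocyte mask of the same layer, and
candidates with encirclement ≥ 0.5 are accepted. Working at track level
guarantees a fragment visible in two layers is counted once, and no blob
can be both part of a counted cell and an accepted debris particle.

### Parameters and their defaults

Three groups of parameters live in `detection_params()`:

* **Assay-defining rules** — overlap fraction 0.60 (of the smaller area),
  cell cutoff 6.5 µm (strict), debris window [2.5, 6.5] µm (closed), layer
  support ≥ 2. These encode the counting rules themselves.
* **Encirclement operationalization** — ring width 1 µm, ring coverage
  threshold 0.5. "Encircled by astrocyte signal" is inherently qualitative;
  both knobs are exposed, and the astrocyte mask used here is a *presence*
  mask (half the threshold offset, no morphology) so thin arcs register.
* **Calibration choices** — blur σ 0.5 µm; threshold block 30 µm; threshold
  offset 70 (0–255 scale, ≈ 0.27 in [0, 1]); morphology radius 0.5 µm.
  These were fixed once by a calibration study over ten seeded synthetic
  scenes, chosen to make the measured Feret diagonal unbiased against the
  generating diameter (residual bias +0.10 µm, SD 0.16 µm). Larger blur or
  smaller offsets dilate every mask by a sizable fraction of a micrometre,
  which matters enormously at a 6.5 µm decision boundary; a morphology
  radius of 2 px erases sub-3 µm fragments outright. The chosen offset
  sits near half the typical object contrast, placing the mask edge at the
  blurred edge midpoint.

All physical parameters are converted through a per-axis calibration
(µm/px in x and y, z step in µm), because a 600 × 400 µm ROI rastered at
1024 × 1024 px has unequal pixel pitch per axis. Structuring elements are
isotropic in pixels (radius converted with the mean pitch); at this
calibration the anisotropy error is below one pixel for the radii used.

## The synthetic scene generator

`generate_scene()` renders what the detector needs to be tested against,
with exported ground truth (object list, band polygon, per-channel truth
masks recorded before noise):

* **Neurons** are spheres of 8–15 µm diameter placed without overlap; each
  sphere's per-layer cross-section follows chord geometry, and centres are
  placed between two z planes so every cell spans ≥ 2 consecutive layers —
  exercising the overlap-linking rule realistically.
* **Debris** are single-plane disks of 2.5–6.5 µm, each surrounded by a
  GFAP annulus painted *in contact* with the fragment (debris sit attached
  to astrocyte branches) over 80% of its circumference by default. Decoy
  fragments without a ring can be added to test rejection.
* **Astrocytes** (GFAP somata with radiating processes) and **microglia**
  (smaller somata, thinner processes) span two layers.
* An optional **pyramidal band** (`band_spec()`) is a solid bright band of
  configurable thickness and orientation. The default scene has no band:
  the detector deliberately performs no watershed splitting of touching
  somata, so a packed band is a single giant blob; cell-recovery scenes are
  band-free and thickness scenes are band-only.
* **Background** is a flat offset plus a planar gradient (which defeats any
  global threshold, motivating the adaptive one) and additive Gaussian
  noise, applied last; intensities are quantized to the 16-bit grid so a
  written stack round-trips bit-identically. Identical seed and spec give
  bit-identical output.

Default counts per scene follow the study conditions the detector is
validated under: 25 neurons, 15 encircled debris, 10 astrocytes, 12
microglia in a 600 × 400 µm, 3-layer stack. Noise SD 0.03 and contrast
0.45 are calibration choices (acquisition noise is not specified by the
assay); they produce a signal-to-noise ratio at which the detector should,
and does, recover counts within ±10% for cells and ±15% for debris.

What the generator does **not** emulate: optical point-spread convolution,
spectral bleed-through, refractive aberration, clustered or touching
somata, and irregular (non-spherical) morphologies. Passing recovery tests
on these scenes therefore demonstrates the correctness of the counting
rules and their thresholds, not the detector's performance on real tissue —
that is what the Bland–Altman module, fed with manual counts, is for.

## Pyramidal-layer thickness

`pyramidal_thickness()` measures the band on the maximum-intensity NeuN
projection (one thickness per ROI): a global Otsu threshold separates the
band from background — the detector's local-mean threshold is deliberately
*not* used here, since any region wider than the averaging block is
hollowed out to its own local mean — the column-wise foreground profile is
smoothed with a small vertical Gaussian, and each column's band extent is
the longest contiguous run above half that column's peak. Columns without a
band are excluded; if more than half the columns lack one the result is
flagged and the mean undefined. A guard requires the foreground/background
median separation at the Otsu split to exceed 0.1, so a signal-free raster
is flagged rather than split mid-noise. A rotation angle can be supplied
for non-horizontal bands, and `thickness_from_polygon()` accepts
hand-drawn band outlines (mean vertical extent) for manually delimited
layers.

At zero noise the estimator recovers a synthetic 60 µm band within two
pixel pitches, doubles when the generated band doubles, and is invariant to
intensity scaling and horizontal translation (all asserted in the tests).

## Method agreement

`bland_altman()` implements the classical agreement statistics between the
algorithm and a manual reference (optionally the mean of two observers,
`observer_mean()`): bias (mean of differences), precision (SD of
differences), limits of agreement (bias ± 1.96 SD), percent bias (bias over
the grand mean of pairwise means — the denominator is a convention choice,
flagged in the documentation), and a two-sided regression of differences on
means as the proportional-trend test (α = 0.05; the named "tendency of the
difference to increase with the mean" needs an operational test, and the
regression slope is the standard one). The two methods are declared
*interchangeable* when |percent bias| < 10% and no trend is detected. With
zero spread in the differences the trend test is undefined and reported as
no-trend.

## Study summaries

* `brain_plasma_ratio()` — per-animal brain (ng/g) over plasma (ng/mL)
  concentration; undefined when the brain sample is missing. `cbd_pk()`
  ships the published per-rat concentrations at 1 h and 24 h post-dose,
  and `pk_summary()` reproduces the printed summary rows. Two printed
  quirks are handled explicitly: the published 24 h dispersion rows follow
  the sample-SD convention although labelled SEM (`mean_sem(convention =
  "sd")` reproduces them; the default computes the true SEM), and the
  printed 1 h brain mean is inconsistent with its own per-rat values, so
  it is not used as a reference anywhere.
* `discrimination_index()` — (TN − TF)/(TN + TF), bounded in [−1, 1],
  antisymmetric; `nor_di()` applies the ≥ 2.5 s familiarization inclusion
  rule.
* `kindled_at()` — the second of the first pair of consecutive injections
  scoring Racine stage ≥ 4; `ptz_screen_excluded()` implements the
  two-initial-stage-5 sensitivity screen; `seizure_summary()` tabulates
  mortality fractions, injections-to-kindled and latency/duration
  summaries per group. Inferential statistics (log-rank, ANOVA, etc.) are
  deliberately left to standard routines.

## Numerical conventions and degenerate inputs

* Pixel coordinates are 0-based, half-open, origin top-left; pixel `(i, j)`
  is centred at `((j − 0.5)·µm/px_x, (i − 0.5)·µm/px_y)`. ROI rectangles
  are half-open in µm; nested crops compose exactly in pixel space.
* Channel identity is always explicit (stored names or a configured
  RGB mapping; the cyan GFAP pseudocolour travels in the blue plane by
  default), never inferred from intensities.
* The adaptive-threshold block is clamped to the raster and must be ≥ 3 px;
  a constant raster yields an empty mask; empty masks and empty scenes flow
  through every stage and yield zero counts.
* Linking ties are broken by overlap area then centroid distance, making
  the track partition deterministic; the test suite checks it against an
  independently coded brute-force oracle on hundreds of random scenes, and
  the Feret measurement against an O(n²) corner-pair oracle.

## Problem sizes used in the tests

Unit tests run on reduced scenes (200 × 150 µm at the standard pixel
pitch) chosen to exercise every rule; the acceptance checks run ten
full-size scenes (600 × 400 µm, 1024 × 1024 px, 3 layers) for detector
recovery, 100 random scenes for the linking oracle, 100 random paired
series for the agreement oracle, and 1000 random seizure logs for the
kindling rule. Recovery tolerances (cells within [0.9, 1.1] of truth,
debris within [0.85, 1.15], pooled over ten seeds) were fixed at the
calibration stage, before the acceptance tests were written.

## Known limitations

* Touching somata are not split (no watershed); dense cell packing is out
  of the detector's scope and the band is measured morphometrically
  instead.
* Microglial activation-state morphology and GFAP intensity densitometry
  are not implemented.
* The thickness estimator assumes one dominant, roughly horizontal band
  after optional rotation.
* The greedy linker is exact in the tested regimes but is not a globally
  optimal bipartite matcher; with heavily fragmented masks the choice of
  tie-break can matter.
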