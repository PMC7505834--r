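---
title: "Repeatability of OCTA binarization and quantification: models and methods"
author: "octarep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeatability of OCTA binarization and quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octarep)
```

## The problem

Quantification of en-face optical coherence tomography angiography (OCTA)
images — vessel area density (VAD), skeletonized vessel length (VL), and
choriocapillaris (CC) flow-deficit count and size — depends on a
binarization step that turns the grayscale angiogram into a flow mask.
Many thresholding algorithms are in use across the literature, and their
repeatability, across repeat acquisitions of the same eye and across
contrast adjustments of the same image, is not a given.  This package
implements the full analysis chain — contrast transforms, image
processing, the eleven global and local thresholds, the metrics, and
ICC-based repeatability statistics — together with a synthetic phantom
generator so the chain can be exercised and tested without patient images.

## Image model and processing steps

Images are 8-bit (0–255) square en-face rasters with a physical pixel
pitch derived from the device export grid: a 3-mm field sampled at
1024/429/304 pixels gives pitches of about 2.93/6.99/9.87 µm, so the
common 15-px local threshold radius corresponds to 43.9, 104.9 and
148.0 µm on those grids — one of the package's calibration checks.

Processing steps mirror common practice:

* **Contrast gain** about mid-grey: `f(p) = gain (p − 128) + 128`,
  rounded half away from zero, clipped to [0, 255].  Gains of 1.5 and
  2.0 are the study levels.  On the non-clipped range the map is
  strictly increasing and injective — the property behind the
  contrast-invariance of rank-based thresholds.
* **Histogram normalization** stretches the histogram to [0, 255] after
  saturating 0.3 % of pixels (0.15 % per tail); anchors come from the
  cumulative histogram.
* **CLAHE** with tile side 127 px, 256 bins and maximum slope 3: per-tile
  histograms are clipped iteratively (excess redistributed to bins below
  the limit until the slope bound holds) and pixel mappings are
  bilinearly interpolated between tile centres.  A slope limit of 1
  forbids any contrast change, so the output equals the input up to
  rounding — a sharp correctness check.
* **Rigid registration** by phase correlation with a rotation search
  (coarse grid, parabolic refinement).  On phantoms with known jitter it
  recovers translations within 0.5 px and rotations within 0.25°.  The
  first acquisition of each subject is the reference.  Failure (no
  correlation peak, constant image) degrades to the identity transform
  with a warning rather than aborting a cohort run.

## The eleven thresholds

Five global methods work on the 256-bin histogram: the legacy iterative
intermeans variant that zeroes the extreme bins ("Default"), Huang's
fuzzy-entropy minimizer, IsoData (Ridler–Calvard fixpoint), the floored
mean, and Otsu (smallest maximizer of between-class variance).  Six local
methods threshold each pixel against a statistic of its circular disc
neighbourhood (radius 15 px by default, replicate padding): Bernsen
(mid-grey with a low-contrast rule), mean, median (lower median),
Niblack (`mean + k·sd`), per-neighbourhood Otsu, and Phansalkar (on
intensities normalized to [0, 1]).  One tie rule is used everywhere:
white (flow) iff `p > t`.  Method constants default to the conventions
of the widely used plugin family (Bernsen contrast 15, Niblack k 0.2,
Phansalkar k 0.25 / r 0.5 / p 2 / q 10) because the originating studies
name the tools but not the constants; all are overridable.

Two border conventions are provided.  Replicate padding is the default,
matching the plugin family.  A "clip" mode intersects the neighbourhood
with the image; under clip semantics a radius covering the whole image
makes every local method coincide exactly with its global twin, which
the tests exploit as a consistency oracle.  The two conventions differ
only within one radius of the border.

The implementation keeps a sliding 256-bin histogram per image column,
so local statistics cost O(radius) per pixel rather than O(radius²);
global methods and their exhaustive-search oracles live in plain R.

## Metrics

VAD is the white-pixel percentage.  VL counts skeleton pixels after
Zhang–Suen thinning (an optional Euclidean mode sums inter-pixel steps,
√2 for diagonals).  Thinning with simultaneous deletion can erase an
isolated 2×2 blob outright; since the medial axis of such a blob is a
single pixel, `skeletonize()` retains one pixel per vanished component,
preserving component counts.  CC flow deficits are the 8-connected
components of the inverted binary image — no size filter, edge-touching
components included (both are option flags, since the original particle
analyses do not state their settings).  With zero deficits the mean size
is reported as missing, never as 0.  Derived quantities such as
flow-deficit percentage are deliberately not computed (they are linear
in VAD and would duplicate information).

## ICC models

Repeat-acquisition repeatability uses the one-way random-effects ICC,
`ICC(1) = (MSB − MSW) / (MSB + (k − 1) MSW)`, estimating the proportion
of total variance attributable to between-subject variation.  Contrast
repeatability uses a two-way mixed model with fixed condition (gain)
columns; we implement the single-rater consistency form
`ICC(3,1) = (MSR − MSE) / (MSR + (k − 1) MSE)`, the natural choice when
fixed conditions shift means systematically (absolute-agreement ICC(2,1)
is available as an option).  Contrast ICCs are computed per repeat image
and arithmetically averaged over the repeats.  Negative estimates are
retained (one-way bounded below by −1/(k−1)): they indicate low
repeatability, often simply little between-subject variation.  Zero
total variance yields a missing ICC with a warning, never 0 or 1.
Classification uses strict cutoffs: high above 0.80, low below 0.50,
exactly 0.80/0.50 counts as moderate.  ΔICC is processed minus
unprocessed, binned for heat-map reporting at ≤0, deciles to 0.5, >0.5.

Both estimators are tested to 1e-10 against independent `lm`/`anova`
decompositions, and the one-way estimator recovers
σ²ᵦ/(σ²ᵦ + σ²ᵥᵥ) within Monte-Carlo error at n = 50, k = 3.

## The phantom generator

No patient images are distributed, so every downstream stage is
exercised on synthetic phantoms that emulate the two en-face appearance
classes:

* **Retinal plexus** (FRL/SCP/DCP): bright branching trunks grown from
  the border inward by a stochastic branching random walk with caliber
  decay, over a capillary mesh built from band-pass-filtered noise, a
  dark central foveal avascular zone (FAZ) disc, and background.
* **Choriocapillaris**: a stationary granular texture with
  Poisson-placed dark elliptical flow deficits recorded in a truth mask.

Repeat acquisitions of a subject share one template and differ by a
smooth elastic perturbation of vessel appearance, a sub-pixel rigid
shift and small rotation (≤3 px, ≤1°, giving registration something to
correct), a per-acquisition gain/offset, and fresh additive speckle.
Hierarchical seeding (master → subject → acquisition) makes cohorts
bit-reproducible; zero jitter reproduces templates exactly, driving
repeat ICCs to 1 (or missing under zero variance) — both ends of the
nesting property are tested.

### Between-subject structure, and why it looks the way it does

The default full-range phantoms are built to sit in the low
contrast-repeatability regime that clipping induces in retinal images.
Getting there shaped several design choices, all of which are subject- or
scan-level traits a clinician would recognise:

* Healthy maculae carry near-identical vascular area, so the structural
  VAD component is pinned: trunks are grown until a target area fraction
  is reached and the capillary coverage is set by a band quantile.  The
  density trait perturbs both only slightly (sd 0.02).
* What differs markedly between scans is signal: a subject-level gain
  (sd 0.18), a spatial vignetting field (uneven signal across the
  field), and a defocus blur (σ between 0.3 and 1.1 px).  All three are
  largely absorbed by adaptive thresholds at baseline but interact with
  the clip points of the contrast gains, producing the subject-specific
  contrast responses that depress the two-way consistency ICC.
* The capillary band sits below mid-grey (0.36 of full scale), so
  contrast gains push it toward 0 — the "loss of small vessels" regime —
  while the CC texture is centred near mid-grey (0.50), the fixed point
  of the contrast transform, which is the homogeneity mechanism that
  keeps CC quantification comparatively robust under re-contrasting.
* CC deficits are planted at 25 per mm² (sd 6) with 30 µm mean radius,
  giving the dark histogram mass that anchors global thresholds and the
  contrast-stable between-subject signal (deficit burden) that carries
  the CC ICC.

With these defaults the retinal mean contrast-ICC falls below the CC
mean, as in real data, but the simulated gap (≈0.05–0.1) is much smaller
than the real-eye gap: a smooth, low-dimensional family of subject
traits cannot reproduce the full idiosyncratic interaction between
heterogeneous retinal content and clipping.  Consequently that
directional comparison is evaluated on three pooled cohort replicates
(13 eyes × 3 repeats each) to average cohort-level trait-sampling noise,
and an individual small cohort can still invert the direction.  This is
the main caveat on what passing tests show about real data; the
bit-exact properties (radius calibration, monotone invariance of local
median, metric identities, estimator oracles) do not share it.

The "no-clip" switch (`intensityRange = c(65, 191)`) restricts template
*and* acquisition intensities to the range on which gains 1.5 and 2.0
remain injective.  There, local-median binaries are bit-identical across
gains — order statistics commute with strictly increasing maps, and the
`p > t` comparison is preserved — so the averaged two-way mixed ICC of
VAD and of flow-deficit count equals 1.00 exactly, reproducing the
degenerate entries that rank-based local thresholding yields under pure
contrast re-scaling.  The acquisition clamp matters because speckle is
Gaussian and otherwise unbounded.

What the phantoms do **not** model: biophysical flow, projection
artifacts, pathology (the emulated cohorts are healthy), vendor-specific
export tone curves, and inter-device differences beyond the pixel grid.

## Numerical conventions

Rounding is half-away-from-zero throughout (R's `round` is half-even);
8-bit conversion divides by the source full-scale maximum; the lower
median is used for even neighbourhood counts (only possible in clip
mode); Otsu ties break to the smallest threshold; degenerate
single-occupied-bin histograms return that bin with a warning; the
Bernsen low-contrast rule assigns the whole neighbourhood white iff the
mid-grey is at least 128.  Problem sizes in the tests — 96–256-px
phantoms, cohorts of 8–13 subjects, three repeats — were chosen as the
smallest grids on which a 15-px disc radius and the FAZ geometry remain
meaningful.

## Factorial harness

`runExperiment()` takes one `experimentConfig()` and produces a
`ResultsBundle`: the per-image metric table, repeat-acquisition ICC
tables per processing variant, ΔICC tables against the unprocessed
baseline, and averaged contrast-ICC tables.  Processing variants are
applied to the original images independently, never chained, and the
contrast analysis operates on the unregistered images (it re-contrasts
the same image, so alignment is irrelevant).  The run manifest (seeds,
parameters, package version) suffices to reproduce every table
bit-exactly, which is itself a tested invariant.  "Averaged per image"
is interpreted as: one subjects × gains grid per repeat index, ICC per
grid, arithmetic mean over the repeats.

```{r example, eval = FALSE}
cfg <- experimentConfig(nSubjects = 8, nRepeats = 3,
                        plexuses = c("SCP", "CC"), sizePx = 160,
                        profiles = list(DeviceProfile("synthetic", 160)))
rb <- runExperiment(cfg)
head(resultsContrastICC(rb))
```

## Known limitations

* The synthetic contrast-repeatability gap between retinal and CC images
  is directionally correct but much smaller than in real eyes (above).
* Registration assumes small rigid motion; large rotations (>2°) are
  outside the search window by default.
* The "Default" global threshold follows the legacy intermeans variant
  with zeroed extreme bins; other software lineages differ in how they
  treat the extremes, which matters on spike-at-zero histograms.
* Real-eye ICC tables cannot be reproduced without the original patient
  images; all quantitative claims here are about the synthetic cohorts
  and the deterministic worked examples.
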