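---
title: "Superpixel delimitation of the choroid in OCT B-scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superpixel delimitation of the choroid in OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choroidsps)
```

## The problem and the measurement model

Swept-source OCT B-scans resolve the choroid — the vascular layer between
the retinal pigment epithelium (RPE) and the sclera — as a textured,
moderately reflective band whose lower boundary is irregular and poorly
captured by single-point thickness calipers. `choroidsps` instead delimits
the whole choroidal cross-section with supervised superpixel clustering
and summarizes it with three per-eye quantities:

* **CA** (choroidal area): the number of pixels in the segmented region,
  in px². Pixel counts, not microns: the metric deliberately avoids the
  device-specific axial scaling and the optical-distance ambiguities of
  thickness measurements.
* **COID** (choroidal optical image density): the mean 8-bit gray level
  over the segmented region, kept at float precision internally and
  printed at 2 decimals.
* **CD** (choroidal density): the ratio CA / COID. Because CD is
  recomputed from the unrounded CA and COID, the identity
  `CD * COID = CA` holds to floating-point precision. One published
  worked example (CA = 82,072, COID = 70.95, CD = 1358.22) is not
  internally consistent with CD = CA / COID; the two consistent examples
  confirm the ratio definition, which this package treats as
  authoritative.

The pipeline is a five-stage chain, each stage 8-bit in / 8-bit out with
half-away-from-zero rounding for cross-platform determinism:

1. **Conversion and crop.** RGB exports are collapsed with BT.601 luma
   weights (device exports are pseudo-grayscale, so any sensible weights
   coincide on r = g = b pixels); the 1024 × 992 frame is cropped to
   992 × 992. The source material does not say from which side columns
   were removed; we remove them symmetrically (floor of the excess on the
   left) because HD-line scans are fovea-centered, and expose the choice
   in configuration.
2. **Denoising and contrast.** A normalized Gaussian kernel of radius
   `ceil(3 sigma)` (default sigma = 1 px, reflective boundaries) reduces
   speckle; a frequency-domain median filter suppresses periodic
   power-line artifacts; global histogram equalization flattens the
   histogram before the expert views the superpixel overlay.
3. **Superpixelation.** Deterministic grayscale SLIC (below).
4. **Selection.** An expert — or a band-criteria surrogate — picks the
   superpixels covering the choroid; their union is the region of
   interest. The region may legitimately consist of more than one
   4-connected component; metrics are computed over the union.
5. **Metrics.** CA, COID, CD as defined above, measured on the cropped
   grayscale image *before* contrast enhancement so that COID keeps its
   acquisition gray scale.

## The spectral median filter

"Frequency-domain median filter" is not a textbook primitive, so its
numerics are a package decision, recorded here: the image is Fourier
transformed, a 3 × 3 (configurable, odd) median filter is applied to the
centered log-magnitude spectrum, the DC bin is restored exactly, and the
image is rebuilt from the filtered magnitude with the original phase.
Periodic artifacts appear as isolated spectral peaks, which a median
replaces with their smooth surroundings, while broadband image content
passes essentially unchanged; pinning DC preserves the mean gray level
exactly (before the final 8-bit clip). On a planted single-frequency
stripe the filter removes well over 90% of the artifact bin's energy.
Whether the original implementation filtered magnitude, log-magnitude or
used a notch design is unknowable from its description; log-magnitude was
chosen because spectra are approximately log-smooth, making isolated
peaks maximally salient to a median.

Histogram equalization uses the classic cumulative-distribution map
`T(v) = round(255 (cdf(v) - cdf_min) / (N - cdf_min))`, which is monotone
by construction. Note a discrete fact the test suite relies on:
equalization relabels gray levels and can only merge them, so the
histogram entropy is preserved when the map is injective (well-populated
levels) and can drop slightly when sparse tail levels collide; it never
increases.

## Deterministic grayscale SLIC

Superpixels are computed by local k-means in the (intensity, x, y) space:

* K seeds on a regular `ny × nx` grid (`ny × nx ≤ K`,
  `S = sqrt(N / K)` the nominal interval), each moved to the
  lowest-gradient position in its 3 × 3 neighborhood (strict improvement
  only, so flat regions keep the grid position);
* for `iterations` rounds, every pixel within a 2S × 2S window of a
  center is assigned to the center minimizing
  `D = sqrt(dI² + (dxy / S)² m²)`, ties to the lowest center index, and
  centers are recomputed as cluster means;
* labels are renumbered 1..K; connectivity enforcement then splits any
  fragmented label into its 4-connected components and merges every
  component smaller than `S² / 4` into its largest 4-adjacent neighbor.

There is no randomness anywhere: identical input and parameters give a
bitwise-identical label raster. The compactness weight `m` trades
intensity fidelity against shape regularity; on a fixed noisy fixture the
mean boundary length does not increase as `m` grows through {1, 10, 40}.

Two design notes. First, the source procedure exposes exactly the triple
(superpixel count, iterations, shape regularity), which identifies a
SLIC-style algorithm but not its constants; the defaults here (K = 400,
10 iterations, m = 10) give superpixels roughly 50 px across on a
992 × 992 scan, comparable to the granularity visible in published
overlays, and all three are exposed in configuration. Its actual values
were operator-defined and never published. Second, the windowed
assignment is equivalent to an unwindowed global assignment whenever each
pixel lies within 2S of every center (small K relative to the frame) or
when `m` is large enough to keep assignments local; the test suite
exploits both regimes to check the compiled implementation against an
independent brute-force oracle in R, bit for bit. Center means are
accumulated in extended precision specifically so that the two routes
agree exactly rather than to rounding.

## Supervised selection and its batch surrogate

The procedure this package models is semi-automatic: an expert inspects
the numbered overlay and groups the choroidal superpixels. Interactive
use passes explicit label ids. Batch runs and tests use `band_criteria`:
a superpixel qualifies if its mean gray level lies in an intensity window
and its centroid depth lies in a row window, optionally measured relative
to a per-column anchor — the brightest (RPE) row of each column, median
smoothed. The anchor makes the depth window follow retinal tilt, which is
why recovered areas on sheared scans stay within a couple of percent of
the untilted recovery. The expert's post hoc "correction" step is exposed
only as re-selection (adding or removing labels); no richer editing is
modeled.

## The synthetic B-scan generator

Clinical images cannot ship with the package, so every stage is validated
against a seeded generator that emulates the geometry the pipeline
relies on: five horizontal bands (vitreous 10, neuroretina 120, RPE 210,
choroid 60, sclera 90 by default, interfaces at 0.30, 0.50, 0.55, 0.75 of
the height), darker elliptical vessel lumina inside the choroid band
(included in the ground-truth mask, as the choroidal region of interest
comprises stroma and vessels), multiplicative gamma speckle with unit
mean and L looks (the standard coherent-imaging model; variance 1/L), an
optional additive horizontal-frequency sinusoid for power-line artifacts,
and an optional linear column-wise shear for retinal tilt. The
ground-truth mask is the exact pre-noise band, so `compute_metrics` on
the clean image reproduces the generator's truth identically.

What the generator does *not* emulate — curved (foveal) layer geometry,
depth-dependent signal roll-off, shadowing under large vessels, motion
artifacts, A-scan resampling — bounds what passing tests show: they
validate the algorithmic contract (partitioning, selection, metric
arithmetic, tilt robustness, statistical behavior), not clinical
segmentation accuracy on real eyes.

Cohort simulation applies group-level deltas (default: choroid band
thinned ×0.90 with gray level +7 for an MS-like group, ×0.80 and +14 for
a PD-like group — the direction of published group differences: smaller
CA and higher COID in disease, stronger in PD) plus per-subject jitter
(interface depths, SD 0.006 of the height; band intensities, SD 2 gray
levels). Magnitudes are configurable and are not claimed to be clinically
calibrated.

## Group statistics

Metrics are compared across groups with a one-way ANOVA
(`F = (SSB/(k−1)) / (SSW/(N−k))`, p from the upper F tail) and pairwise
Welch t-tests with Bonferroni adjustment (`p_adj = min(1, p m)`), flagged
at alpha = 0.05. The post hoc procedure used in the original analysis is
unnamed; Welch–Bonferroni was chosen as robust and assumption-light, and
may be slightly more conservative than alternatives such as Tukey HSD
(noted, not implemented). Normality screening is assumed rather than
re-tested; the metrics module documents the parametric assumption. With
two groups, F equals the squared pooled-variance t statistic — one of the
identities the suite checks to 1e-9. Degenerate inputs are pinned:
all-identical data give F = 0, p = 1; zero within-group variance with
distinct means gives F = Inf, p = 0.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to exercise the full pipeline
meaningfully on a desktop: synthetic scans of 496 × 496 px (half the
clinical frame) for recovery checks — noise-free recovery is exact, CA
under L = 8 speckle stays within 10% of truth, tilted-scan recovery
within 2% of untilted — 64 × 64 fixtures for the 50-replicate
partition/connectivity suite, 25 eyes per group for the
disease-direction cohort (ANOVA p < 0.001, all three pairs flagged), and
200 five-per-group replicates for the null calibration (rejection rate
within binomial tolerance of 5%). Tie-breaks are fixed everywhere
(lowest center index in SLIC, row-major scans, strict-improvement seed
perturbation), quantization is half-away-from-zero, and COID is never
re-rounded before entering CD.

## Known limitations

* The band-criteria surrogate needs intensity/depth windows appropriate
  to the image's gray scale; with histogram equalization enabled the
  choroid's equalized level depends on the whole image, so batch
  recovery configurations disable equalization (the expert-facing
  overlay path keeps it).
* CA is reported in px² only; no micron calibration is attempted.
* Sub-layer separation (Haller/Sattler), vascularity indices and
  OCT-angiography quantities are out of scope.
* K after connectivity enforcement may differ from the requested
  superpixel count (merging and splitting both occur); the requested K
  bounds the count only before enforcement.
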