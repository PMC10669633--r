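# choroidsps

Supervised superpixel segmentation of the choroid in OCT B-scan images.

The choroid — the vascular layer between the retinal pigment epithelium
and the sclera — thins and changes reflectivity in neurodegenerative
disease, but its lower boundary is irregular, so single-point thickness
calipers are noisy. `choroidsps` delimits the whole choroidal
cross-section of a B-scan with a deterministic grayscale SLIC superpixel
pipeline and quantifies it with three per-eye metrics:

* **CA** — choroidal area: pixels in the segmented region (px²);
* **COID** — choroidal optical image density: mean 8-bit gray level of
  the region;
* **CD** — choroidal density: CA / COID (dimensionless).

The pipeline follows a five-step chain: 8-bit conversion and square crop
(1024 × 992 → 992 × 992), speckle/artifact filtering (Gaussian low-pass,
frequency-domain median filter, histogram equalization), SLIC
superpixelation with the distance
`D = sqrt(dI² + (dxy/S)² · m²)`, supervised (or criteria-driven)
superpixel selection, and metric computation. Metrics from multiple eyes
are compared across groups (e.g. controls vs. multiple sclerosis vs.
Parkinson disease) with one-way ANOVA and Welch–Bonferroni post hoc
tests. A seeded synthetic B-scan generator with exact ground-truth masks
makes every stage testable without clinical data.

Intended users: researchers analyzing exported OCT B-scans (TIFF/PNG)
who want a device-independent, reproducible choroid delimitation and the
CA/COID/CD summary, from R or from a shell.

## Worked example

Segment a synthetic B-scan with speckle (L = 8 looks) and recover its
metrics; the band criteria select superpixels with mean gray 40–80 that
sit below the bright RPE anchor band:

```r
library(choroidsps)

scan <- generate_bscan(synthetic_spec(speckle_looks = 8, seed = 42))
cfg <- pipeline_config(
  preprocess = preprocess_params(equalize = FALSE),
  selection = list(mode = "band",
                   criteria = band_criteria(c(40, 80), c(5, 150),
                                            anchor = "brightest")))
res <- process_bscan(scan$image, cfg)
res$metrics
#> CA = 45316 px^2, COID = 63.72, CD = 711.14
c(scan$true_CA, round(scan$true_COID, 2))
#> [1] 49104.00    58.13
```

The recovered area is within 8% of the ground truth on this speckled,
vessel-laden scan (noise-free scans recover exactly). The CD definition
reproduces the published healthy worked example from its printed CA and
COID:

```r
choroid_density(154940, 51.22)
#> [1] 3024.99     # printed as 3025.15 from the unrounded COID
```

For clinical exports, pass file paths instead:

```r
res <- run_process(c("eye_OD.tif", "eye_OS.tif"), cfg, output_dir = "out")
run_stats("out/metrics.csv", output_dir = "out")   # needs >= 2 groups
```

A command-line front end with `process`, `synth` and `stats` subcommands
is installed at `system.file("cli/choroidsps.R", package = "choroidsps")`.

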