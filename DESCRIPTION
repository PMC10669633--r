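Package: choroidsps
Title: Supervised Superpixel Segmentation of the Choroid in OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delimits the choroidal layer in optical coherence tomography (OCT)
    B-scan images with a deterministic grayscale SLIC superpixel pipeline and
    computes three per-eye summary metrics: choroidal area (CA, px^2), choroidal
    optical image density (COID, mean 8-bit gray level) and choroidal density
    (CD = CA / COID). Includes image conversion and square cropping, speckle
    denoising (Gaussian low-pass), frequency-domain median filtering of periodic
    artifacts, histogram equalization, supervised and criteria-driven superpixel
    selection, region properties and boundary extraction, a seeded synthetic
    B-scan generator with ground-truth masks, and one-way ANOVA group
    comparisons with Welch-Bonferroni post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
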