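Package: chipmorph
Title: Lumen-Width Quantification, Endothelial Morphometry and
    Longitudinal Statistics for Organ-on-Chip Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the projected width of an endothelial lumen from
    low-magnification fluorescence images of a microfluidic channel
    (cross-channel intensity profiles with Otsu-threshold edge detection),
    computes cell-shape descriptors (area, fitted-ellipse aspect ratio,
    Feret diameter and angle) from integer label masks with border-object
    removal and a minimum-area filter, and analyses the resulting
    longitudinal per-chip width tables with a repeated-measures linear
    mixed model with unstructured covariance, a 95 percent
    confidence-interval-overlap divergence-day rule, and Kruskal-Wallis
    tests with Dunn's post-hoc comparisons.  Ships seeded synthetic-data
    generators (fluorescence scenes with ground-truth edges, non-adjacent
    elliptical cell masks, longitudinal cohorts with unstructured
    covariance and monotone dropout) so every stage is testable without
    raw microscopy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
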