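Package: spherochip
Title: Multiscale Image Cytometry for Anchored-Droplet Spheroid Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for microscopy of spheroids cultured in
    anchored-droplet microfluidic chips. Detects the hexagonal anchor array
    by matched filtering, segments spheroids from bright-field (gradient +
    watershed) or fluorescence (automatic threshold) images, computes
    morphometry (area, equivalent diameter, shape index) and classifies
    objects into cell units, aggregates and spheroids, fits exponential
    spheroid-formation kinetics, performs single-cell fluorescence cytometry
    (nuclei/dead-cell peak detection, radial r/R positions, volume-effect
    correction of albumin signal, BrdU gating, neighbour distances),
    quantifies region-resolved drug-perfusion death kinetics and co-culture
    core metrics, and applies the matching statistical comparison and
    Tukey-box reporting conventions. Includes a synthetic chip-image
    generator with planted ground truth so the whole pipeline is testable
    without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    EBImage,
    minpack.lm,
    tiff,
    yaml,
    withr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
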