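Package: optomet
Title: Spatiotemporal Metabolic Imaging with Ratiometric Planar Optodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ratiometric sensor-foil (planar optode)
    imaging of dissolved oxygen and extracellular pH in adherent cell
    cultures. Converts two-channel fluorescence image stacks into calibrated
    pO2 and pH maps via Stern-Volmer and sigmoid calibration models, corrects
    uneven illumination with a one-point adjustment, extracts region-of-interest
    time series and 96-well plate read-outs, estimates cell-number-normalised
    oxygen consumption rates (OCR) and extracellular acidification rates (ECAR)
    from the linear range of depletion curves, counts stained nuclei for
    normalisation, detects metabolically active regions in analyte maps, and
    compares groups with one-way ANOVA and Tukey HSD. Includes a
    reaction-diffusion micro-respirator simulator that renders realistic
    sensor-foil frame stacks and nuclei images with known ground truth, so the
    whole pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
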