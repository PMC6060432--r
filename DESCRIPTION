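Package: glucofret
Title: Quantification of Intracellular Glucose Dynamics from Ratiometric
    FRET Biosensor Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify intracellular glucose dynamics in neurons
    expressing a ratiometric FRET glucose biosensor. Provides a synthetic
    two-channel movie generator with a mechanistic glucose transport and
    consumption model, translation registration by phase correlation,
    pixelwise ratio imaging with nucleus-excluded somatic ROI trace
    extraction, baseline drift correction and relative-ratio statistics
    (timepoint values, windowed slopes, group mean and SEM), exact
    two-sided Fisher and Mann-Whitney U tests implemented from scratch,
    and single-cell RT-multiplex-PCR occurrence analysis of a glucose
    metabolism gene panel with genotype comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
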