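Package: gelchar
Title: Characterization and Predictive Design of Collagen I Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantitative characterization of collagen I hydrogels
    and empirical fabrication-to-property modelling. Implements turbidity
    polymerization kinetics metrics (total absorbance change, half-time, rate,
    lag time), an automated confined-compression modulus pipeline (contact
    detection, thickness validation, robust loess smoothing, 5-15% strain
    regression, rejection rules), Frangi-vesselness fiber segmentation with
    distance-map fiber and pore morphometry for confocal reflectance images,
    stripe-bleach FRAP diffusivity estimation from Gaussian profile variance
    growth, and coded-unit full-factorial regression models of hydrogel
    properties with sensitivity analysis and desirability-based inverse
    design. Synthetic-data generators with known ground truth are provided
    for every modality so the full analysis chain is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
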