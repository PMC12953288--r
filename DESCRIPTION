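Package: steatomorph
Title: Lipid Droplet Morphometry and Histology-MRI Steatosis Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-pathology style quantification of hepatic steatosis and its
    concordance with MRI proton density fat fraction (PDFF). Segments lipid
    droplets on calibrated adipophilin-style tissue rasters, classifies them by
    cross-sectional area into tiny, small and large subtypes, computes
    proportionate-area morphometry, assigns steatosis grades by the pathologist
    rule (large-droplet hepatocyte fraction) and by PDFF thresholds, and runs a
    full grading-discordance analysis: rates and cross-tabulation, stratified
    group comparisons, univariable and multivariable logistic modelling with a
    collinearity screen, correlation and paired-test batteries, quadratic
    size-composition curves, and a precision-based sample-size calculation.
    Includes calibrated synthetic image and cohort generators with known ground
    truth, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
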