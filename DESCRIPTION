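Package: crowdcell
Title: Crowdsourced Labeling Analysis for Blood Smear Cell Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing crowdsourced morphology labels on peripheral
    blood smear cells (circular, elongated/sickle, other deformations).
    Implements plurality-vote consensus aggregation of fixed-size worker
    panels with agreement stratification, an evaluation-metric suite for
    imbalanced cell classes (per-class accuracy, the sickle-cell diagnosis
    support score, class-balance accuracy variants, Matthews correlation,
    F-measures, two-class merging), a binomial independence model predicting
    consensus accuracy from individual worker accuracy, Chan-Vese active
    contour segmentation with small-object removal and per-cell crop
    extraction, and seeded generators for synthetic smear scenes and
    correlated worker vote streams so every stage is testable end to end.
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
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
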