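Package: sulfoscreen
Title: Sulfate-Focused Untargeted Metabolomics for Administration-Route
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An untargeted LC-HRMS/MS workflow for screening steroid sulfate
    conjugates in equine urine and discriminating administration routes of a
    shared drug (oral versus intramuscular altrenogest). Provides monoisotopic
    mass and negative-ion m/z arithmetic for molecular formulas, annotation of
    the six sulfate-diagnostic MS/MS signals (SO3-, HSO3-, SO4-, HSO4-
    fragment ions and SO3, H2SO4 neutral losses) with intensity-ratio and
    maximum-abundance summaries, k-means (k = 2) classification of features
    into sulfated and non-sulfated classes, pooled-QC anchored LOWESS drift
    normalization, empirical-Bayes moderated differential analysis with
    three-tier volcano categorization, ppm-based matching against a
    theoretical steroid sulfate list, and Monte-Carlo cross-validated random
    forest evaluation of biomarker panels. A synthetic administration-study
    generator reproduces the design structure the analysis assumes (two
    routes, dense 0-504 h urine collection, technical triplicates, pooled QCs,
    injection-order drift) with ground truth for validation.
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
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
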