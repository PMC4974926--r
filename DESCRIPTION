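Package: beesem
Title: Piecewise Structural Equation Models for Bee Reproduction and
    Floral Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying how flower diversity, temporal
    stability of floral resources, elevation and fire history shape the
    reproduction of cavity-nesting solitary bees. Implements piecewise
    structural equation modelling via d-separation basis sets and Fisher's C,
    AIC-based model selection, partial-correlation path coefficients,
    cross-species meta-analysis of path coefficients with Fisher's z
    transform and bootstrap percentile confidence limits, rarefied flower
    richness and diet-generalization indices (rarefied degree and inverse
    Simpson), and a synthetic-data generator that emulates the trap-nest and
    floral-survey sampling design so every stage is testable without field
    data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
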