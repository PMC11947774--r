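Package: glysol
Title: Solid-Liquid Equilibrium Modeling of Fructose Solubility in Glycerol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling the solubility of sugars in non-aqueous
    solvents, built around the fructose-glycerol system. Provides a
    group-contribution activity-coefficient engine covering the UNIFAC
    family (Staverman-Guggenheim or Larsen-modified combinatorial,
    solution-of-groups residual, and an optional Wertheim-type association
    contribution for hydrogen-bonding hydroxyl groups), a solid-liquid
    equilibrium solver that turns melting properties and activity
    coefficients into solubility curves, a fitter for the three-parameter
    Nyvlt solubility correlation, and a comparison pipeline that scores
    model variants against experimental data by root-mean-square and
    average relative deviations. Ships the experimental fructose-in-glycerol
    solubility dataset and melting-property constants as bundled fixtures,
    plus a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
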