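Package: dietfba
Title: Compile Growth-Medium Recipes into Nutritional Constraints for
    Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Translates chemically complex growth-medium descriptions
    (components such as tryptone or yeast extract, given in g/L, plus pH
    and oxygen regime) into quantitative exchange-reaction bounds for
    constraint-based metabolic models. Provides tabular readers for
    recipes, component composition tables and speciation rules; a diet
    compiler that decomposes complex components into molecules, converts
    mass to molar concentrations and injects environmental compounds
    (water, oxygen, protons); an identifier mapper from diet compounds to
    model exchange reactions across nomenclature dialects; a flux balance
    analysis core with a built-in bounded-variable simplex solver
    reporting fluxes, duals and reduced costs; a reduced-cost
    troubleshooter that ranks missing nutrients and repairs diets; and a
    supplementation scanner that quantifies growth-yield responses to
    nutrient additions. Includes deterministic toy-model and toy-recipe
    generators with closed-form optima for testing.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
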