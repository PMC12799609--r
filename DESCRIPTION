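Package: gasferm
Title: Carbon Accounting and Bioenergetics for CO2-to-VFA-to-PHB Gas Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of mixed-culture gas
    fermentation campaigns that convert CO2 and bicarbonate into volatile
    fatty acids (VFA) and polyhydroxybutyrate (PHB). Provides a molecular
    formula parser with fractional stoichiometry for elemental carbon
    accounting, ideal-gas CO2 dosing calculations, standard Gibbs
    free-energy feasibility checks for acetogenesis and PHB synthesis with
    element-balance diagnostics, an input/output carbon ledger with residual
    metabolite closure, from-scratch one- and two-way ANOVA for enrichment
    comparisons, and a seeded synthetic generator of enrichment-campaign
    datasets for end-to-end testing.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
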