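Package: gutflux
Title: Diet-Constrained Community Metabolic Modeling of the Gut Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating gut microbiome metabolism under defined
    dietary conditions. Converts food-intake records and food-composition
    tables into metabolite uptake fluxes (mmol/day), profiles dietary energy
    and macronutrients against reference-intake ranges, normalizes
    genome-coverage tables into cutoff-filtered relative abundances, joins
    per-taxon genome-scale metabolic models into abundance-weighted
    community models with lumen, diet and fecal boundaries and biomass
    coupling constraints, runs flux variability analysis to estimate net
    metabolite secretion and uptake, and decomposes community fluxes into
    per-taxon contributions to call short-chain fatty acid producers and
    prebiotic responders. Includes a synthetic-data generator (toy fermenter
    models, Dirichlet cohorts, a small food-composition database) so the
    whole pipeline is testable without external model repositories.
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
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
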