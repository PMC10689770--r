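Package: colpress
Title: Colonization Pressure and Establishment Richness from the Global
    Live Vertebrate Trade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying alien species in the live terrestrial
    vertebrate trade. Harmonizes trade records from heterogeneous sources
    (regulatory trade databases, enforcement records, zoo inventories and
    free-text online listings), resolves species names through a
    length-sorted key index, classifies every traded species-by-country
    combination as alien or native against country-level native ranges,
    aggregates colonization pressure and establishment richness per
    country, fits linear mixed models with a biogeographic-realm random
    intercept, performs all-subsets AICc multimodel inference with
    conditional coefficient averaging, and computes donor-to-recipient
    species-flow networks among eight world economic regions. A seeded
    synthetic-data generator with a recoverable truth ledger supports
    end-to-end testing and parameter-recovery studies.
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
    utils,
    withr,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
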