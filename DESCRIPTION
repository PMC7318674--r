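Package: umbrellar
Title: Cost-Effective Prioritization of Umbrella Species for Threat Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Budget-constrained, cost-effectiveness prioritization of umbrella
    species for threatened-species management. Combines species range overlap,
    species-specific threat profiles, and power-law area-cost models with
    diminishing returns into a greedy maximum-gains selection that maximizes
    the number of species benefitting from threat abatement under a fixed
    budget. Includes a no-double-counting benefit accrual ledger, optimistic
    and pessimistic benefit scenarios, an exhaustive small-instance oracle,
    cost-exponent sensitivity analysis, reference-list efficiency comparison,
    and a synthetic assemblage generator for gridded landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
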