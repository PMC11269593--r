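Package: batwind
Title: Seasonal Habitat Models and Wind-Turbine Siting Conflict Analysis for Migratory Bats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-annual-cycle habitat modelling and wind-energy siting conflict
    analysis for a migratory bat. Provides presence-background maximum-entropy
    niche models with linear, quadratic and product features and L1
    regularization tuned by AICc, omission-rate habitat classification,
    a weighted multi-criteria wind-turbine siting suitability score,
    turbine/habitat impact tabulation, seasonal conflict maps and roost-buffer
    overlap summaries, together with a seeded synthetic-landscape generator so
    the whole pipeline runs end-to-end with known truth and no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    geosphere,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
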