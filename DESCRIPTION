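Package: nemschile
Title: Scoring and Reliability Analysis for the NEMS-S-CHILE Store Food-Environment Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Chilean adaptation of the Nutrition Environment
    Measures Survey for Stores (NEMS-S-CHILE) as an executable scoring
    engine: a packaged 62-food / 27-measure checklist organised by NOVA
    food-processing group, store-level scores spanning -30 to 100 points
    built from availability, quality, variety and price-comparison
    components, inter-evaluator reliability statistics (percent agreement,
    Cohen's kappa, intraclass correlation coefficients) with the banded
    interpretation scales used for store audits, store-type comparison of
    score distributions, and a seeded generator of synthetic
    paired-evaluator audits so the full pipeline can be exercised without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
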