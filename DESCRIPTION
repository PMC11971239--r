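Package: limbwear
Title: Free-Living Upper-Limb Prosthesis Wear and Physical Behaviour Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for concurrent wrist-worn and thigh-worn activity
    monitoring of upper-limb prosthesis users in free-living conditions. Converts
    raw wrist tri-axial acceleration into legacy activity counts, detects
    prosthesis wear and donning/doffing events with a run-length non-wear
    algorithm, classifies each day's thigh-monitor behaviour epochs into at-home
    and away-from-home time using sleep-anchored stepping transitions, and fuses
    the two streams into pre/post don-doff stepping profiles and daily
    summaries. Includes a seeded synthetic-cohort generator so every stage can
    be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
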