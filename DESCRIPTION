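Package: dietwf
Title: Water Footprint Accounting for Food-Based Dietary Guideline Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the total, green, blue, and grey water footprint (WF) of
    national recommended dietary patterns from per-food WF data (L per kg of
    production weight). Implements the pattern-construction conversions used by
    food-based dietary guidelines (edible-portion to production weight, cooked
    to dry legume mass, aquaculture share of seafood, composite-food rules,
    serving-weighted group averages, min/max-average patterns with proportional
    rescaling to a target energy), aggregation into weekly and per-capita daily
    footprints with component shares and food-group contributions, and
    food-substitution scenario analysis (equal-mass and equal-protein swaps).
    Ships the Italian, Spanish, and US guideline patterns as plain-text
    fixtures together with a synthetic-data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
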