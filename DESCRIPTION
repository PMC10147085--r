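Package: fuzzyMCDA
Title: Fuzzy Multi-Criteria Decision Analysis with PROMETHEE, TOPSIS and
    Weighted-Sum Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria decision analysis for alternatives rated on
    linguistic scales. Implements fuzzy PROMETHEE I/II outranking with
    triangular fuzzy numbers, Yager-index defuzzification and the six
    classical preference functions, together with weighted-sum and TOPSIS
    comparators, one-at-a-time weight-sensitivity analysis, and a
    replication harness that calibrates the unstated preference-function
    configuration of a published tau PET radiotracer ranking. Ships that
    15-alternative x 4-criterion decision problem as a worked fixture and
    generalizes to any alternatives x criteria problem supplied as CSV
    plus JSON/YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
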