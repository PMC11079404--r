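Package: beesafe
Title: Fuzzy Decision Support for Pesticide Environmental Safety Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores the environmental safety of pesticides on a 0-10 scale
    with a Mamdani fuzzy inference system built from five ecotoxicological
    parameters: soil half-life, the agroecology environment quality quotient
    (AEQ, the reciprocal honey-bee toxic unit), contact LD50 toward honey
    bees, a bee exposure-likelihood score, and the maximum residue limit.
    Provides membership-function primitives, an expert-weighted rule-base
    generator, centroid defuzzification with an exact closed-form
    verification oracle, the AEQ sub-model that derives bee exposure from
    field doses, tidy assessment pipelines, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
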