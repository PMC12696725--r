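Package: hostcost
Title: Host-Plant Energetics of Herbivorous Larvae from Syringe Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the energetic cost of host-plant use in
    polyphagous insect larvae. Converts raw stop-flow (syringe) respirometry
    CO2 traces into CO2 production rates (VCO2), computes larval growth rate
    and growth cost (CO2 produced per gram of mass gain), fits the allometric
    mass-scaling of metabolic rate with host-specific coefficients, and tests
    host-plant effects with family-level random-intercept mixed models,
    Type II Wald chi-square tests and Tukey-adjusted pairwise contrasts. A
    seeded synthetic-data generator produces split-brood cohorts and raw
    analyzer traces with known parameters so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
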