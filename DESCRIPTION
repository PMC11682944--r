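Package: beecotox
Title: Dietary Pesticide Risk Quotients and Colony Profit Modelling for
    Honey Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes acute and chronic dietary risk quotients (RQs) for
    honey bee colonies from pesticide residue concentrations measured in
    pollen and nectar, classifies them against regulatory levels of
    concern (acute cage RQ = 0.4, acute field RQ = 0.2, chronic
    RQ = 0.03), and evaluates a colony-level beekeeper profit model under
    lethal and sublethal pesticide-exposure scenarios, including
    break-even colony-health values and a sensitivity analysis. Includes
    a seeded censored-lognormal residue simulator so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
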