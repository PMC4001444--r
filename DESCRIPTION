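Package: phenoevo
Title: Individual-Based Simulation of Budburst Phenology Evolution Along
    Climate Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit, individual-based simulation of the
    microevolution of budburst timing in forest tree populations along an
    elevational climate gradient. Couples a thermal-time budburst model and a
    surrogate daily carbon/water balance with tree demography (carbon-starvation
    mortality, reserve-driven fecundity, exponential-power pollen and seed
    dispersal, density-dependent recruitment) and a ten-locus additive
    quantitative-genetics model of the budburst forcing requirement. Provides a
    synthetic daily climate generator with elevational lapse adjustment,
    scenario presets contrasting heritability, mortality and frost-damage
    regimes, and tidy analysis helpers for selection differentials, responses
    to selection and elevational range shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
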