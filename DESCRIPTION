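Package: phycogas
Title: Gas-Exchange Modelling and Rubisco-Kinetic Diagnostics for Algal
    Carbon-Concentrating Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative framework for deciding whether an aquatic
    photosynthetic organism's gas-exchange physiology exceeds what its rubisco
    kinetics permit without a carbon-concentrating mechanism. Provides
    temperature-adjusted Henry's law gas solubility, Q10 adjustment of rubisco
    kinetic parameters with phase-aware unit handling, CO2 compensation-point
    modelling and oxygen-response slope extraction over kinetic parameter
    combinations, freshwater dissolved inorganic carbon speciation across pH,
    and a data-reduction pipeline for aquatic-chamber CO2-response,
    light-response and pH-comparison experiments (headspace correction,
    Michaelis-Menten and compensation-point fits, Kok respiration), together
    with a seeded synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
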