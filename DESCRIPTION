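Package: islandcarbon
Title: Stock-and-Flow Carbon Budget Modelling for Small Island
    Social-Ecological Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A configurable stock-and-flow simulator for the annual carbon
    cycle of a small inhabited island, modelled on the Gouqi Island
    (East China Sea) social-ecological system. Seven carbon stocks
    (atmospheric exchange, forest, wetland, mussel shell, soil and two
    methane pools) are advanced by twenty-four named process fluxes
    covering tourism, transport, desalination, waste, mussel aquaculture
    and the forest and tidal-wetland ecosystems. The package aggregates a
    simulated year into an emissions/sinks budget with a carbon credit and
    percentage shares, and applies policy scenarios (transport and ferry
    electrification, macroalgae carbon-sink farming) to quantify savings
    toward carbon neutrality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
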