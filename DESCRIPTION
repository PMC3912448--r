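Package: snapsoc
Title: SNAP Mass-Balance Model of Soil Organic Carbon in Grazed Tropical
    Grasslands
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the SNAP annual mass-balance model of soil organic
    carbon (SOC) dynamics for grazed tropical grasslands and savannas.
    From five site drivers (mean annual rainfall, grazing intensity, fire
    frequency, plant lignin+cellulose fraction, and soil sand content) the
    model evaluates annual carbon input fluxes from plant decomposition and
    herbivore dung, grazing-compensated aboveground production through a
    leaf-area-index response, microbial respiration losses, and a
    closed-form equilibrium SOC stock to 40 cm depth. Includes Monte Carlo
    propagation of regression-coefficient and driver errors, one-at-a-time
    sensitivity analysis, validation against a packaged eight-site Serengeti
    exclosure-experiment table, re-fitting of the empirical sub-models for
    transfer to other grasslands, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
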