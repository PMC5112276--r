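Package: isochamber
Title: Chamber-Based CO2 Isotopologue Flux Analysis for Drought and
    Recovery Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to turn raw valve-switched CO2-isotopologue streams from
    paired shoot/soil flux chambers into physiological fluxes and isotope
    signals: net assimilation, transpiration, stomatal conductance, soil
    respiration, on-line photosynthetic 13C discrimination and the delta13C
    of soil-respired CO2. Includes treatment-level drought-effect and
    recovery-day statistics (error propagation, exact rank-sum test, mixed
    models) and a seeded synthetic chamber simulator that emulates a
    control/drought beech-sapling experiment so the whole pipeline can be
    validated closed-loop against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    nlme,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
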