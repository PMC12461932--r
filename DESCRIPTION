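Package: pickering
Title: Quantitative Analysis of Biocatalytic Pickering-Emulsion Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify enzyme- and nanoparticle-laden oil/water
    interfaces in Pickering emulsions. Converts pendant-drop interfacial
    tension time series into surface pressures with a trailing-slope
    steady-state criterion and an adsorption cooperativity factor; extracts
    amplitude, phase and interfacial storage/loss moduli from oscillatory
    shear traces and analyzes amplitude sweeps for the linear viscoelastic
    plateau, yield point and flow point; measures droplet diameter,
    interfacial peak concentration, layer thickness at a fixed concentration
    level and bulk concentration from confocal droplet images via rotated
    diameter profiles and a fluorescence intensity-to-concentration
    calibration. Includes a synthetic-data generator with known ground truth
    for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
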