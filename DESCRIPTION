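Package: shelltherm
Title: Solar-Weighted Shell Reflectivity and Phylogenetic Thermal Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how solar reflectivity of intertidal
    gastropod shells relates to microhabitat and heating rate. Reads and
    splices UV-visible and near-infrared reflectance spectra, computes
    solar-weighted reflectivity over configurable wavebands against a
    bundled reference solar irradiance spectrum, fits Bayesian Gaussian
    mixed models with a phylogenetically structured species effect by
    Markov chain Monte Carlo, analyses field heating-rate experiments
    with rock-temperature residualization, and simulates calibrated
    synthetic datasets (Yule trees, spectra, reflectivity and heating
    studies) for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
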