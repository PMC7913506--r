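Package: hemospect
Title: RGB Camera-Based Spectral Imaging of Hemoglobin Derivatives and
    Tissue Oxygenation in Skin
Version: 0.1.0
Authors@R:
    person("hemospect", "developers", email = "hemospect@example.org",
           role = c("aut", "cre"))
Description: Transcutaneous quantification of methemoglobin, oxygenated and
    deoxygenated hemoglobin, melanin, total hemoglobin and tissue oxygen
    saturation from ordinary RGB camera images. Diffuse reflectance spectra
    are reconstructed from the three camera channels by Wiener estimation,
    converted to absorbance, and unmixed by a two-stage multiple regression
    whose empirical inverse model is calibrated on Monte Carlo simulations
    of light transport in a two-layer (epidermis/dermis) skin model. A
    synthetic phantom generator renders ground-truthed RGB images and image
    time series so that the complete pipeline can be exercised and validated
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
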