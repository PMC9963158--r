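Package: relaxcryst
Title: Enthalpy Relaxation and Crystallization-Time Prediction for
    Amorphous Lyophilizates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the modified stretched-exponential (MSE) enthalpy-relaxation
    model of Pikal and Kawakami to short isothermal-microcalorimetry (IMC)
    power-time records of freeze-dried amorphous formulations, extracts the
    composite relaxation time tau-beta, determines long-term crystallization
    times either from IMC exotherm maxima or from weekly DSC feature
    trajectories during storage, and correlates relaxation with
    crystallization to predict the physical stability of new lyophilization
    processes. Includes extractors for glass-transition and
    crystallization-peak features from deconvolved modulated-DSC curves, and
    a synthetic-data generator that emulates the full study design with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
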