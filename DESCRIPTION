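Package: droprheo
Title: Surface Dilational Rheology and Adsorption Modelling for
    Oscillating-Drop Tensiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for oscillating pendant-drop tensiometry of
    soluble surfactant layers, built around the multicomponent cationic
    surfactant ethyl lauroyl arginate (LAE). Extracts the complex surface
    dilational modulus from drop area and surface tension time series by
    Loess smoothing and harmonic least-squares regression, fits the
    Lucassen-van den Tempel diffusional viscoelasticity model to modulus
    spectra, quantifies nonlinear (second-harmonic) distortion of the
    tension response, and models equilibrium surface tension isotherms of
    ionic surfactant mixtures with a coupled Frumkin/Gouy-Chapman
    adsorption model, including critical micelle concentration detection.
    A synthetic-data generator emulates the tensiometer so every stage can
    be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
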