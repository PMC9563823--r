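Package: nirtea
Title: NIR Chemometrics for Tea Authentication and Taste-Compound Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric modelling of near-infrared diffuse-reflectance
    spectra of green tea. Provides spectral pretreatments (multiplicative
    scatter correction, standard normal variate, derivatives,
    Savitzky-Golay filtering), NIPALS partial least squares regression
    with PRESS-based latent-variable selection under leave-one-out
    cross-validation, synergy-interval and backward-interval PLS variable
    selection, Mahalanobis-distance discriminant analysis on principal
    component scores for geographical-origin authentication, and a
    synthetic tea-spectra generator with known ground truth for validating
    every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, signal
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
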