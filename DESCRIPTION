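Package: nirtex
Title: NIR Spectroscopy Calibration for Table-Grape Texture and Soluble Solids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for calibrating near-infrared (NIR)
    diffuse-reflectance spectra of intact table-grape berries against
    texture-profile-analysis parameters (hardness, springiness, cohesiveness,
    chewiness) and total soluble solids. Implements spectral pre-treatments
    (SNV, MSC, Savitzky-Golay smoothing and derivatives, mean centering,
    min-max scaling), PCA/Mahalanobis and chi-square critical-limit outlier
    screening, SIMPLS partial least squares with leave-one-out
    cross-validation and jack-knife coefficient inference, wavelength
    selection by Monte Carlo uninformative variable elimination and by
    significant beta coefficients, Kennard-Stone sample partitioning, and a
    small feed-forward neural network regressor. A synthetic-data module
    generates berry populations and spectra with the statistical structure
    the analysis assumes, so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
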