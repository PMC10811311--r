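Package: piglung
Title: Reference Equation for Normal Lung Weight in Domestic Pigs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and use of an allometric reference equation linking
    body weight to lung weight index (lung weight / body weight, g/kg) in
    healthy female domestic pigs of 16-50 kg, the weight range typical of
    porcine models of ARDS and ventilator-induced lung injury. Provides
    quantitative-CT lung weight computation from Hounsfield-unit volumes,
    log-linear fitting of the exponential reference model with parameter-wise
    95% confidence bands, train/validation splits and k-fold
    cross-validation, Bland-Altman agreement analysis with confidence
    intervals on the bias and limits of agreement, a synthetic cohort
    generator for simulation studies, and a normalization-error framework
    quantifying how body-weight normalization biases lung-edema comparisons
    across animals of different size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
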