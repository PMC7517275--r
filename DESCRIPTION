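Package: drstissue
Title: Tissue Classification from Diffuse Reflectance Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for discriminating healthy tissue types (fat,
    skin, nerve, bone, muscle) from diffuse reflectance spectra in the
    220-1100 nm range. Provides spectral preprocessing (reflectance
    computation, normalization, linear detrend, Savitzky-Golay smoothing,
    segment-shift alignment), detection of nine characteristic spectral
    landmarks tied to hemoglobin, water and lipid absorption bands, pairwise
    gradient features ranked by one-way ANOVA F, principal component
    reduction, five classifiers (LDA, QDA, Gaussian naive Bayes, k-nearest
    neighbors, CART), multiclass evaluation with the sensitivity/specificity
    conventions used in the ex vivo porcine study the pipeline models, and a
    seeded hierarchical synthetic-spectra generator so every stage is testable
    without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    MASS,
    rpart,
    class,
    withr,
    jsonlite
Config/testthat/edition: 3
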