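Package: chromanose
Title: Colorimetric Sensor Array Electronic-Nose Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for colorimetric sensor array (dye-spot)
    electronic-nose experiments on meat authentication. Extracts per-spot
    RGB colour-change profiles from before/after-exposure array images,
    reduces them by principal component analysis with cumulative-contribution
    component selection, classifies samples by Fisher linear discriminant
    analysis and by an extreme learning machine, and predicts adulteration
    levels with a back-propagation neural network trained with momentum.
    Includes a synthetic sensor-array generator that emulates the collinear,
    overlapping response structure of real dye arrays so every stage can be
    exercised without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    tools,
    S4Vectors,
    SummarizedExperiment,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
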