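Package: carbonscape
Title: Red-Edge Band Screening, Random-Forest Species Mapping, CASA Net
    Primary Productivity and Maximum-Entropy Suitability Zoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for mapping a
    target tree species from multi-date 8-band imagery and assessing its
    carbon sequestration capacity and climatic suitability. Provides
    Jeffries-Matusita separability screening of band/index combinations
    (with red-edge bands), a random-forest classification harness with
    confusion-matrix accuracy metrics (OA, PA, UA, F1, Kappa), a CASA
    light-use-efficiency model for monthly and annual net primary
    productivity with natural-breaks zoning and carbon-total aggregation,
    and a maximum-entropy presence-background species distribution model
    with replicate AUC evaluation, variable importance and four-class
    suitability zoning. A seeded synthetic-data module generates scenes,
    samples, climate and bioclimatic covariates with known ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
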