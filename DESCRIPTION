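Package: orthomorph
Title: Clustering of Postural Blood-Pressure Morphology from Beat-to-Beat Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses beat-to-beat active-stand blood pressure recordings:
    quality screening, interpolation to a uniform 1-second grid, extraction of
    three systolic blood pressure change features (early-phase nadir,
    stabilization point at 40 s, late-phase nadir period), k-means++ clustering
    of the feature vectors into orthostatic morphologies with stability and
    quality diagnostics, reassignment of participants with a normal orthostatic
    response into a reference group, and estimation of frailty-indicator odds
    ratios for each morphology against that reference via 2x2 tables and
    logistic regression. A synthetic-cohort generator produces recordings and
    linked frailty covariates with the statistical structure the analysis
    assumes, so the whole pipeline runs without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
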