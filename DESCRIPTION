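Package: mixhill
Title: Mixture Effect Prediction for Steroidogenesis Dose-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits constrained Hill (three-parameter logistic, slope fixed at 1)
    concentration-response curves to single-chemical steroidogenesis assay data,
    gates fitting on a Kruskal-Wallis significance test, and predicts fixed-ratio
    mixture effects under Concentration Addition (CA), Independent Action (IA)
    and Generalized Concentration Addition (GCA). Includes per-chemical
    contribution curves on the mixture-concentration axis, an applicability rule
    that refuses prediction for mixtures with opposing-direction components, and
    a synthetic-data generator emulating the H295R triplicate assay design so the
    whole pipeline can be exercised without access to raw assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
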