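Package: uaextract
Title: Response-Surface Optimization and Kinetic Modelling of
    Ultrasound-Assisted Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, optimizing and modelling solid-liquid
    extraction of plant bioactive compounds, built around a three-factor
    Box-Behnken design workflow: second-order response-surface regression on
    coded factor levels with lack-of-fit ANOVA, Derringer-style desirability
    optimization over the coded factor cube, two-stage extraction-kinetics
    models (film theory, unsteady diffusion through plant material, and
    Ponomaryov's empirical equation) fitted by linearized and nonlinear least
    squares, and spectrophotometric quantification of total anthocyanin and
    total phenolic content. Ships a worked dataset on ultrasound-assisted
    extraction from purple-fleshed sweet potato together with synthetic-data
    generators for every stage of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
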