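Package: coolwedge
Title: Myocardial Perfusion Heterogeneity and Hypothermic Ventricular
    Electrophysiology Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial heterogeneity of 3D myocardial blood-flow
    maps by the relative-dispersion fractal dimension, computes myocardial
    perfusion reserve and six-segment statistics, and simulates the
    electrophysiological consequences of therapeutic hypothermia and
    dialysis-induced ischemic stress with a human ventricular cell model
    embedded in a monodomain transmural wedge producing pseudo-ECGs.
    Includes a synthetic-data generator for left-ventricle-shaped perfusion
    volumes with prescribed mean flow and fractal dimension, paired
    normothermia/hypothermia cohorts, exact Wilcoxon signed-rank
    comparisons, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
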