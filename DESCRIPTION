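Package: asymadstrat
Title: Risk Stratification of Asymptomatic Alzheimer's Disease from
    Targeted CSF Peptide Panels
Version: 0.1.0
Authors@R:
    person("EHBS", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for stratifying the risk of progression from asymptomatic
    to symptomatic Alzheimer's disease using targeted cerebrospinal fluid
    (CSF) peptide panels. Implements Gaussian-mixture and Youden-index
    biomarker gating, dual-classifier recursive feature elimination with a
    permutation null for peptide panel selection, proximity-based sub-typing
    of asymptomatic biomarker-positive individuals via t-SNE embeddings and
    k-nearest-neighbour voting, and a scaled event-based model of disease
    progression with Markov chain Monte Carlo inference and probabilistic
    patient staging. Includes a synthetic-cohort generator emulating the
    statistical structure such analyses assume, for validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
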