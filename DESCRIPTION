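Package: daraopt
Title: Optimal Daratumumab Scheduling in a Phenotype-Switching Myeloma Model
Version: 0.1.0
Authors@R:
    person("James", "Holloway", email = "jholloway@example.org", role = c("aut", "cre"))
Description: Three-compartment ordinary differential equation model of
    multiple myeloma under anti-CD38 monoclonal antibody (Daratumumab)
    therapy, with reversible CD38 expression switching, drug-induced loss
    of expression, off-target mortality of healthy marrow cells, and a
    saturating (Michaelis-Menten) immune response. Provides a fixed-step
    Runge-Kutta simulator, an optimal-control solver based on Pontryagin's
    maximum principle (forward-backward sweep) for linear, quadratic and
    mixed running costs, an independent direct-transcription oracle,
    a classifier for the qualitative form of optimal dosing schedules
    (bang-bang, bang-singular, gapped, cyclic, indefinite maintenance),
    and experiment drivers that map these treatment regimes over the
    parameter space.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
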