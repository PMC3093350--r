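Package: gatedtx
Title: Gated Markov Chain Models of Transcriptional Initiation and Pausing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time Markov chain models of transcription in which a
    promoter chain (pre-initiation complex assembly through promoter-proximal
    pause release) is coupled to a two-state enhancer chain through a single
    gated transition. Builds composite promoter-by-enhancer chains for
    initiation-regulated (IR) and elongation-regulated (ER) topologies from a
    shared rate vector, computes first-passage-time distributions of the
    induction-to-expression delay (Laplace transforms, moments, phase-type
    densities, pinch-point factorization, enhancer-equilibrium reduction),
    renewal-theory statistics of transcript counts with scaffold-reinitiation
    bursting, exact Gillespie simulation of single cells and populations,
    uniform parameter-space sweeps comparing the two regulatory topologies,
    and normalized squared-gradient sensitivity analysis of system properties
    with respect to each jump rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
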