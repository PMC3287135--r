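Package: oscspec
Title: Frequency-Domain Analysis of Stochastic Oscillatory Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterise and compare the behaviour of stochastically
    simulated biochemical reaction networks in the frequency domain.
    Provides a plain-text reaction dialect with optional SBML import,
    alpha-discretization of concentration models to molecule counts,
    quasi-deterministic model conversion, exact stochastic simulation
    (Gillespie direct method), last-observation-carried-forward resampling
    of event trajectories, ensemble-averaged discrete Fourier amplitude
    spectra, a Kolmogorov-Smirnov behavioural distance between spectra,
    signed influence graphs with path-based proximity heuristics, and a
    library of coupled stochastic oscillator models for crosstalk
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
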