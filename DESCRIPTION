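Package: eibalance
Title: Coding and Metabolic Efficiency of Balanced Excitation and
    Inhibition in a Stochastic Hodgkin-Huxley Compartment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a 100 square-micron single-compartment neuron with
    Markov-chain stochastic sodium and potassium channels driven by
    Ornstein-Uhlenbeck excitatory and inhibitory synaptic conductances,
    under three synaptic regimes (excitation only, balanced conductance,
    balanced current).  Quantifies spike rate, interspike-interval
    irregularity, total and noise entropy by the direct method with bias
    correction and word-length extrapolation, mutual information, coding
    efficiency (bits/spike), ATP consumption from integrated potassium
    flux and sodium/potassium pump stoichiometry, and energy efficiency
    (bits/ATP) across a stimulus mean-by-contrast grid.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
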