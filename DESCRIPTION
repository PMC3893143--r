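Package: motifnet
Title: Connectivity-Motif Emergence from Short- and Long-Term Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("motifnet", "developers", email = "motifnet@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of adaptive exponential
    integrate-and-fire neurons whose current-based synapses combine
    Tsodyks-Markram short-term dynamics (facilitating or depressing) with
    the Pfister-Gerstner triplet rule of spike-timing dependent plasticity.
    Provides the standard timing and frequency pairing protocols (including
    pair-based and anti-STDP controls), pairwise connectivity-motif
    statistics with a symmetry index and Bernoulli null model, and a
    Wilson-Cowan mean-field description with short-term plasticity and a
    rate-dependent plasticity drift, used to study how reciprocal motifs
    emerge among facilitating synapses and unidirectional motifs among
    depressing ones.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
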