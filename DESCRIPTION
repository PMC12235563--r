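Package: somasim
Title: Laminar Cortical Column Simulation of Somatosensory Evoked Current Dipoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates source-level current-dipole waveforms (nAm) from a reduced
    conductance-based model of a laminar neocortical column driven by sequences of
    exogenous proximal (feedforward) and distal (feedback) synaptic drives. Includes
    multi-trial experiment configurations for tactile, median-nerve, and laser-evoked
    somatosensory responses, waveform fitting by staged drive-parameter optimization
    (RMSE), one-at-a-time parameter sensitivity analysis, Morlet wavelet
    time-frequency decomposition, and a surrogate evoked-waveform generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
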