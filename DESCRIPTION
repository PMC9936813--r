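Package: olmcell
Title: Reduced OLM Interneuron Model, Theta Spiking Resonance, and Kalman-Filter Conductance Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a reduced single-compartment conductance-based model of the
    hippocampal oriens-lacunosum/moleculare (OLM) interneuron (transient Na, fast
    delayed-rectifier K, A-type K, M-type K, h-current, and leak), generates
    in-vivo-like states from Ornstein-Uhlenbeck excitatory/inhibitory background
    conductances, and analyses spiking resonance at theta frequencies via the
    spike-train power-spectral-density baseline ratio, phase-response curves with
    per-current amplitude changes, and spike-triggered-average slope/spread analyses
    of the underlying ionic currents.  Also implements a robust adaptive unscented
    Kalman filter that estimates maximal channel conductances from noisy
    current-clamp voltage recordings using the same model as the state-prediction
    backbone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
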