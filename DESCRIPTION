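Package: alphaloop
Title: Closed-Loop qEEG Neurofeedback Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A testable closed-loop electroencephalography (EEG)
    neurofeedback simulator and analysis library aimed at mild cognitive
    impairment protocols. Provides synthetic 10-20-montage EEG generation
    from a parametric power-spectrum model (aperiodic 1/f component plus
    Gaussian oscillatory peaks), Welch spectral estimation with
    aperiodic/periodic decomposition, individual alpha peak frequency
    (i-APF) estimation, z-score normative deviation metrics including the
    Clinical Deviation Index (CDI) in both Euclidean and percentage forms,
    a toy-scale standardized distributed inverse solution (sLORETA) with
    region-of-interest power extraction, an adaptive Bayesian reward
    threshold controller holding a configurable success rate (the 70
    percent clinical operating point), synaptic plasticity models
    (Hopfield attractor networks, BCM sliding threshold, homeostatic
    scaling, spike-timing-dependent plasticity) driving a responsive
    virtual subject, and whole-session and longitudinal closed-loop
    orchestration with EDF and CSV/JSON input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
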