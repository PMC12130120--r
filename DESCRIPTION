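Package: truthemg
Title: Facial EMG Correlates of the Illusory Truth Effect
Version: 0.1.0
Authors@R:
    person("truthemg", "maintainers", email = "truthemg@example.org",
           role = c("aut", "cre"))
Description: Simulation, signal processing and multilevel analysis of
    trial-locked facial electromyography (EMG) in repetition-based truth
    judgment experiments. Provides a synthetic-data generator for complete
    experiments (raw multi-channel EMG at 1 kHz plus trial event tables), the
    standard surface-EMG conditioning chain (zero-phase Butterworth band-pass,
    50 Hz notch, rectification, moving-average amplitude envelope), trial-wise
    burst detection with baseline thresholding and a minimum-duration rule,
    AUC/RT feature extraction, outlier screening, and an inference layer with
    random-intercept linear and logistic mixed models, AIC/BIC comparison and
    cluster-bootstrap causal mediation analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
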