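Package: optephys
Title: Optogenetic Stimulation Design and Closed-Loop Electrophysiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing combined optogenetic
    stimulation and multielectrode electrophysiology experiments. Provides
    LED/fiber irradiance calibration, parametric pulse-train synthesis (fixed,
    jittered, Poisson, nested-burst and sinusoidal patterns), LFP and
    spike-band signal chains with median referencing and threshold spike
    detection, multitaper spectral estimation with harmonic removal and
    peristimulus averaging, stimulation-artifact template estimation and
    subtraction, a theta-power-triggered closed-loop stimulation controller,
    and a virtual-subject simulator that generates ground-truth hippocampal
    recordings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
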