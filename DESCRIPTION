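Package: synphys
Title: Analysis of Multipatch Synaptic Physiology Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing synaptic connectivity and short-term
    plasticity from multipatch (paired whole-cell) recordings. Includes a
    synthetic paired-recording generator with known ground truth, sweep
    quality control and spike-aligned averaging, double-exponential
    postsynaptic-potential fitting with region-weighted error, exponential
    deconvolution for train amplitude measurement, an event-driven vesicle
    depletion model with use-dependent replenishment (simulation and
    least-squares fitting), a synapse-detection classifier with
    simulated-EPSP sensitivity analysis, and binomial connectivity
    statistics with Jeffreys intervals and distance profiles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    signal,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
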