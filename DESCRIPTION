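Package: spikecohort
Title: Spike-Train Analysis of Excitation-Inhibition Balance Across Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cohorts of extracellularly recorded cortical
    units in a delayed whisker-detection task: regular-spiking versus
    fast-spiking classification from spike-waveform width, peri-stimulus time
    histograms and window-based evoked-response quantification with
    nonparametric permutation tests, half-maximum response latency,
    optogenetic tagging metrics (fidelity, latency, jitter, opto modulation
    index), interareal functional connectivity via the spike time tiling
    coefficient and jitter-corrected cross-correlograms, and a learning
    modulation index summarising excitation-inhibition changes between novice
    and expert animals. Includes a synthetic session generator with known
    ground truth so every analysis stage is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
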