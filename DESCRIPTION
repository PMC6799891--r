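Package: impedocyte
Title: Label-Free Cell Viability Assessment by Multifrequency Impedance Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for label-free single-cell
    viability assessment with multifrequency impedance cytometry. Generates
    physics-grounded synthetic lock-in (I/Q) recordings from an
    electrode-electrolyte equivalent circuit, detects single-cell transit
    events by robust resistive-pulse detection, extracts per-frequency
    amplitude-change and phase-change features, classifies live versus dead
    cells with a Gaussian-kernel support vector machine, and estimates the
    viability percentage of mixed samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    withr
Suggests:
    kernlab,
    optparse,
    yaml,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
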