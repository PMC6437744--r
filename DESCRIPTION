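Package: etcal
Title: Semiautomated Calibration of Multipad Electrotactile Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating per-pad stimulation amplitudes of a
    16-pad electrotactile forearm array. Implements the two-phase
    semiautomated procedure (a method-of-limits amplitude ramp followed by
    an adjacent-pad fine-tuning sequence), a streamlined variant seeded
    from the cohort 25th-percentile curve, baseline-optimization and
    variability analyses (coefficients of variation, correlation
    structure, L1 effort distances, paired t-tests and repeated-measures
    ANOVA with Greenhouse-Geisser correction), and a virtual-subject
    simulator so the full pipeline can be exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
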