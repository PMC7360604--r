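Package: stressreg
Title: Acute Stress and Cognitive Emotion Regulation Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing acute-stress effects on cognitive emotion
    regulation in mixed between/within designs. Implements a pupillometry
    preprocessing chain (binocular averaging, FIR smoothing, event-locked
    segmentation, physiological range and dilation-speed MAD filters, blink
    gap handling, baseline correction) yielding
    area-under-the-curve-with-respect-to-ground (AUCg) summaries; salivary
    cortisol and alpha-amylase baseline-to-peak deltas and Differential
    Affect Scale scoring; a mixed-design repeated-measures ANOVA engine with
    Greenhouse-Geisser correction, Mauchly's sphericity test, partial eta
    squared, Bonferroni post-hoc tests, assumption checks and Pearson
    correlations; and a seeded synthetic-study generator emulating a 2 x 3
    between-subjects stress-by-sex-hormone design with five within-subject
    emotion regulation conditions, so the whole pipeline is testable without
    any real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
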