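Package: blinkdt
Title: Spontaneous Eye-Blink Rate and Divergent-Thinking Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the relationship between spontaneous
    eye-blink rate (sEBR), a non-invasive proxy of striatal dopamine, and
    divergent-thinking performance. Detects blinks in frontal resting-state
    EEG using amplitude-threshold candidates, tent-shape correlation and
    positive amplitude-velocity ratio criteria; scores Alternative Uses
    Task responses for fluency, flexibility, frequency-based and
    rater-based originality with inter-rater reliability; fits hierarchical
    linear/quadratic and robust regressions of each index on sEBR; and
    estimates curvilinear mediation models with instantaneous indirect
    effects and percentile bootstrap confidence intervals. Includes a
    synthetic-data generator producing EEG-like recordings with known blink
    ground truth and participant tables with a known inverted-U structure,
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
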