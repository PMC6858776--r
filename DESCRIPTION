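Package: vitalex
Title: Rule-Based Extraction of Numerical Clinical Parameters from Narrative Notes
Version: 0.1.0
Authors@R: person("vitalex", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Extracts numerical clinical parameters (vital signs, left
    ventricular ejection fraction, glycated hemoglobin, serum creatinine,
    height, weight) from free-text clinical notes using dictionary term
    matching over a token prefix tree, term-adjacent value and range
    extraction, unlabeled vital-sign number-group detection with
    rule-based filtering and positional variable assignment, and
    per-variable validity tests (viable range, value format,
    condition-symbol policy, unit inference).  Includes note-level and
    value-level evaluation against gold annotations with percentile
    bootstrap confidence intervals, a deterministic synthetic-note
    generator with known gold labels for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
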