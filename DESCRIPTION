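Package: crchain
Title: Analysis of Conditioned Eyelid Response Sequences and Purkinje Cell Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing sequences of conditioned eyelid responses (CRs)
    from eyeblink conditioning experiments with amplitude-contingent
    reinforcement, together with simultaneously recorded cerebellar Purkinje
    cell activity. Provides calibrated trace preprocessing (Savitzky-Golay
    smoothing, second-order velocity, trial exclusion screening), rule-based CR
    event detection (criterion crossing, two-step onset estimation,
    prominence-based multi-CR decomposition, contralateral amplitude
    correction), sequence statistics (conditional second-CR probabilities with
    bootstrap confidence intervals, acquisition/extinction curves, inter-CR
    timing co-variation with permutation shuffle nulls), simple-spike
    firing-rate estimation (inverse inter-spike interval with Gaussian kernel
    smoothing, baseline normalization, CR-onset alignment), and a seeded
    closed-loop session generator emulating the amplitude-contingent training
    protocols, used to validate every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
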