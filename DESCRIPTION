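Package: gazebias
Title: Closed-Loop Audio-Visual Search Simulation and Gaze-Bias Transfer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a gaze-contingent audio-visual search paradigm in which
    tone loudness encodes the distance between gaze and an invisible target
    whose location distribution is biased toward one hemifield, together with
    the full eye-movement analysis chain used to measure transfer of the
    learned spatial bias to free viewing: gap interpolation and trial
    validation, Engbert-Kliegl velocity-threshold saccade detection with
    Hooge-style fixation refinement, oculomotor feature extraction and PCA,
    fixation-density maps, barycenter and point-of-subjective-equality shift
    statistics with one-sided tests, gamma log-link learning-curve models,
    and noncentral-t power / group-sequential design calculations. Synthetic
    observers (a run-and-tumble search agent with a learnable hemifield
    prior, style-parameterised free-viewing generators, and a logistic
    landmark-task responder) replace human participants so that every stage
    of the pipeline can be exercised and validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
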