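Package: pupilfir
Title: FIR Deconvolution and Kernel Modelling for Pupillometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing pupil-size time series recorded during
    cognitive experiments. Implements blink interpolation, zero-phase
    Butterworth band-pass filtering into phasic and tonic components,
    finite impulse-response (FIR) deconvolution of event-locked pupil
    responses by least squares, gamma-family impulse-response models
    (gamma density, Erlang-gamma and double-gamma parameterizations)
    with published canonical parameter sets, GLM-based nuisance
    regression of blink and saccade responses, cluster-based
    permutation tests on response time courses, tonic-phasic
    interaction analyses, and a synthetic-session simulator that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
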