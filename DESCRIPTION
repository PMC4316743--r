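Package: pemotor
Title: Prospective-Error Motor-Primitive Model of Trial-by-Trial Motor Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a motor-primitive model of
    trial-by-trial sensorimotor adaptation in which the recruitment of Gaussian
    tuned primitives is driven by the prospective error, the movement error
    predicted for the upcoming trial. Provides the core learning rule, protocol
    builders for visuomotor-rotation, force-channel and error-clamp schedules,
    ensemble simulation, reproductions of structural learning, feedback
    uncertainty effects, savings, anterograde interference and spontaneous
    recovery, a rival perturbation-prediction model, fitting and resampling
    statistics (exponential learning-speed fits, state-space fits, bootstrap and
    randomization tests), and a synthetic behavioural-data generator emulating a
    three-group rotation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
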