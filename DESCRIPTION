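Package: sarcogait
Title: Sarcopenia Screening from Gait Skeletons and Plantar Pressure Images
Version: 0.1.0
Authors@R: person("sarcogait", "maintainers", email = "maintainers@sarcogait.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying sarcopenia versus normal gait
    from two modalities: 3D skeleton walking sequences (32 joints at 30 fps,
    reduced to a 25-joint graph, trunk-length normalized per frame) classified
    with a spatiotemporal graph convolutional network, and time-averaged
    single-channel plantar-pressure images classified with a residual
    convolutional network. Includes AWGS 2019 hand-grip-strength labeling,
    subject-level class-stratified 4-fold cross-validation with a 20%
    validation split, a seeded synthetic gait and foot-pressure generator for
    download-free testing, and a command-line entry point for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
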