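Package: nfdecode
Title: Incremental SVM Decoding for Real-Time fMRI Neurofeedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of closed-loop motor-imagery neurofeedback
    decoding under nonstationary brain activation. Provides a block-design
    protocol builder, a seeded synthetic 4D fMRI cohort generator that emulates
    the learning-driven shift from widespread to focal activation across
    feedback runs, streaming preprocessing (Gaussian smoothing, masking,
    constant-memory incremental linear detrending), linear support vector
    machine decoding with decision-trace drift correction, a volume-by-volume
    feedback controller, and the evaluation statistics used in real-time fMRI
    decoding studies (task predictive value, pairwise accuracy, repeated
    measures ANOVA, GLM activation maps, and group t-maps of classifier
    weights). The central comparison is between an incremental training
    strategy, in which classifiers are retrained after every feedback run on
    that run's data only, and the conventional static strategy trained once on
    the pre-feedback run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
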