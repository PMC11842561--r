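Package: fbmotor
Type: Package
Title: Closed-Loop Recurrent Network Simulation of Feedback-Driven Motor Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates a recurrent neural network that controls planar
    reaching movements online through delayed error feedback, and adapts
    trial-by-trial to visuomotor rotations through a local feedback-driven
    plasticity rule gated by an eligibility trace. Includes gradient-based
    initial training of the closed loop, scripted behavioural experiments
    (adaptation and washout, error clamps, perturbation-variability sweeps,
    single-target generalization, policy remapping, delay-period
    stimulation), and analyses of the resulting behaviour and population
    activity: take-off angle learning curves, epoch-based activity-change
    signatures, unit classification, velocity decoders, and dual-rate
    state-space fits of learning timescales.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, jsonlite, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
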