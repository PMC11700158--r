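Package: lfpgait
Title: Decoding Gait Weight Shifts from Subthalamic Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for translating bilateral subthalamic
    nucleus local field potentials (LFPs) into a continuous gait-performance
    measure during stepping-in-place tasks. Provides force-plate weight-shift
    quantification (body-weight rescaling, plate merging with mirroring,
    two-second windowed total variation, per-participant normalization),
    causal Butterworth IIR preprocessing, sliding-window dataset assembly, a
    CNN-BiLSTM regression network with relative oscillatory features
    (element-wise division), temporal squeeze-and-excitation gating and an
    ablation-variant factory, subject-dependent training with early stopping,
    Kendall tau evaluation against per-lead beta power, a variance-based
    frequency-band attribution (variation ratio), and a synthetic session
    generator with known neural-to-gait coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
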