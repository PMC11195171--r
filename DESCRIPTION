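Package: lfpcontext
Title: Decoding Latent Social Context from Baseline Amygdala Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting latent brain
    states (social grooming vs. non-social airflow context) from baseline
    local field potentials. Provides a synthetic-session generator with
    block-structured stimulus schedules, context-dependent band-power
    modulation, spike trains and heartbeat series; baseline-window
    extraction from inter-stimulus intervals with a stability criterion;
    complex Morlet continuous-wavelet spectrograms; convolutional neural
    network and radial-basis support vector machine decoders with a
    shuffled-label null protocol, frequency-band ablation and
    cross-nucleus comparisons; spike-triggered-average spectra; and
    heart-rate / respiratory-sinus-arrhythmia physiology via multitaper
    spectral estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
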