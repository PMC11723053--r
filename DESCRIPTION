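Package: mieog
Title: Channel Importance and Compact Convolutional Classification for
    Motor-Imagery EEG/EOG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how much class-relevant information
    electrooculogram (EOG) channels carry in motor-imagery
    brain-computer-interface recordings. Provides an epoched multi-channel
    dataset container, a synthetic EEG/EOG generator with planted
    ground-truth channel effects (1/f background, class-dependent band-power
    modulation, ocular transients, neural leakage into EOG), multitaper
    spectral estimation and zero-phase band-pass filtering, five
    channel-importance methods (histogram mutual information, common
    spatial pattern activations, permutation importance, learned channel
    attention, random subset search), and a compact multi-kernel
    depthwise-separable 1D convolutional network classifier with an
    optional channel-attention front end, trained by Adam with
    cross-entropy loss.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
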