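Package: neurointent
Title: Multimodal Intention Recognition from Motor-Imagery EEG and Scene
    Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decodes user intent for assistive home robots by fusing two
    independently trained recognizers at the decision level. The EEG branch
    classifies four-class motor imagery (left hand, right hand, legs, tongue)
    using physiologically anchored channel selection (fixed C3/Cz/C4 core plus
    variance- and ANOVA-scored candidates), filter-bank common spatial
    patterns, wavelet-packet sub-band energies and nonlinear complexity
    features (sample entropy, spectral entropy, Higuchi fractal dimension),
    classified by one-vs-rest support vector regression. The vision branch
    classifies indoor scenes (kitchen, living room, bedroom) from structured
    features of object-detection outputs (category presence, counts, mean
    confidence, grid confidence maps) with PCA compression and a random
    forest. Posterior probabilities from both branches are multiplied into a
    joint distribution over twelve scene-conditioned robot tasks. Includes
    seeded synthetic generators for motor-imagery EEG (class-conditional
    mu/beta event-related desynchronization over pink-noise background) and
    scene-conditional detection sets, so the full pipeline is testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    ranger,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
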