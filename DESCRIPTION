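Package: observa
Title: Multimodal Analysis of Action Observation: Gaze, Pupillometry, and EEG Mu Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers visually and neurally register
    the efficiency of other people's multi-step actions. Implements dynamic
    area-of-interest (AOI) gaze metrics with front-most conflict resolution
    (dwell, fixation, revisits, gaze-shift transition matrices), temporal
    fixation-probability maps with pixel-wise Welch tests under FDR control,
    gaze-masked "looking video" construction and per-participant
    leave-one-out classification against label-shuffle nulls, pupillometry
    with baseline normalization and time-resolved condition comparison, EEG
    Morlet event-related spectral perturbation with mu-band suppression
    indices, an individualized cluster-based permutation localizer, and a
    least-squares SVM classifier over localizer-selected windows. A synthetic
    cohort simulator generates gaze, pupil, and EEG data with adult-like
    (condition-sensitive) and child-like (condition-insensitive) observer
    profiles so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    png
Config/testthat/edition: 3
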