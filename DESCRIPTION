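Package: ehgelm
Title: Classification of Uterine EHG Recordings via Hilbert-Huang Features
    and Extreme Learning Machines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for distinguishing labour from pregnancy
    electrohysterogram (EHG) recordings. Implements band-pass
    preprocessing of multichannel uterine EMG, empirical mode
    decomposition (EMD) into intrinsic mode functions, analytic-signal
    (Hilbert) instantaneous amplitude, per-channel maximum-amplitude
    feature extraction, and a seedable extreme learning machine (ELM)
    classifier with confusion-matrix and ROC evaluation. Includes a
    synthetic contraction-burst generator so the full pipeline can be
    exercised and tested without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
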