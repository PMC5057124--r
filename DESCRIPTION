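Package: adared
Title: Prediction of A-to-I RNA Editing Sites from Pseudo Dinucleotide Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies adenosine-to-inosine (A-to-I) RNA editing sites in
    fixed-length sequence windows centered on a candidate adenosine. Windows
    are encoded by pseudo dinucleotide composition (PseDNC), which augments
    the 16 dinucleotide frequencies with lambda tiered correlation factors
    computed from six standardized RNA dinucleotide step parameters (Shift,
    Slide, Rise, Tilt, Roll, Twist), and classified with a radial basis
    function support vector machine. Includes grid search over (C, gamma),
    stratified k-fold cross-validation, jackknife evaluation,
    sensitivity/specificity/accuracy/MCC reporting, a (w, lambda) parameter
    sweep, a first-order Markov synthetic benchmark generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
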