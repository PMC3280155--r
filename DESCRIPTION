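Package: promstruct
Title: DNA Structural Profiles and Feature Selection for Promoter Prediction
Version: 0.1.0
Authors@R:
    person("Promstruct", "Developers", email = "promstruct@example.org",
           role = c("aut", "cre"))
Description: Converts core-promoter windows (-200..+50 around the
    transcription start site) into thirteen biophysical structural profiles
    (duplex free energy, stacking energy, DNA denaturation, bending
    stiffness, bendability and others), builds a normalized 13 x 251
    feature matrix, ranks and selects discriminative profile positions with
    filter criteria (information gain, chi-square, ReliefF,
    correlation-based feature selection) and a genetic-algorithm wrapper,
    and evaluates promoter-versus-non-promoter classification with
    cross-validated sensitivity, precision-style specificity, F-measure and
    ROC score. Includes a first-order Markov sequence simulator with
    plantable TATA/Inr elements so the whole pipeline can be exercised
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
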