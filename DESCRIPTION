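Package: smileval
Title: Subjective Value of Smiles: Choice Utilities, Attentional Capture,
    and Dyadic Smile Reciprocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how the subjective value of genuine and
    polite smiles relates to attention and naturalistic dyadic behaviour.
    Implements a logistic choice model that estimates per-participant
    utilities of money, genuine smiles and polite smiles from pairwise
    face choices; value-driven attentional-capture scoring of visual
    search times with a two-by-three repeated-measures ANOVA; facial
    action unit (AU06/AU12) smile classification with windowed
    reciprocity matching at 15 frames per second; and an actor-partner
    interdependence model (APIM) for indistinguishable dyads fitted by
    (full-information) maximum likelihood with bias-corrected bootstrap
    confidence intervals. A synthetic-data generator with known ground
    truth emulates all task datasets so every stage of the pipeline can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
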