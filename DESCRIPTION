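Package: riskdomains
Title: Open-World Risk Factor Domain Classification for Psychiatric
    Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sentence-level topic extraction for psychiatric clinical
    narratives. Builds weakly supervised training corpora by matching
    sentences against a clinician lexicon of domain keywords and
    multiword expressions, mines new multiword-expression candidates by
    TF-IDF over per-domain megadocuments, embeds sentences with a
    pluggable encoder (including a deterministic offline hashed
    encoder), and classifies each sentence into one or more of seven
    readmission risk factor domains (or none, "Other") with a cosine
    similarity baseline, a multilayer perceptron, or a radial basis
    function network with k-means prototypes. Includes per-domain
    open-world score thresholding, macro-averaged multilabel
    evaluation, inter-annotator agreement statistics (Fleiss's kappa
    and the Davies-Fleiss multi-rater kappa), gold-standard
    adjudication helpers, and a seeded synthetic corpus generator for
    end-to-end testing without access to protected health records.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
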