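Package: adsgo
Title: Artificial Dilution Series for Benchmarking Gene Ontology
    Evaluation Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates artificial dilution series (ADS) from any Gene
    Ontology annotated truth set: prediction sets with stepwise-controlled
    signal levels built by shifting annotations to semantic neighbours and
    permuting annotations between genes, plus decoy false-positive sets
    (most-frequent, least-frequent and random term lists).  Scores the
    series with a battery of rank-based (AUC-ROC, AUC-PR), group-based
    (F-max, Jaccard, SimGIC, S-min) and semantic-similarity (Resnik, Lin,
    ancestor-Jaccard) evaluation metrics in unstructured, gene-centric and
    term-centric forms, and summarises each metric by its rank correlation
    with the signal level and by its false-positive signal.  Includes a
    synthetic GO-like ontology and annotation generator so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
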