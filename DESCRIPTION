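Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting stable housekeeping (reference) genes from
    RT-qPCR cycle-threshold data. Implements four established stability
    algorithms (comparative delta-Ct, BestKeeper, NormFinder, geNorm with
    stepwise exclusion), a geometric-mean consensus ranking across methods,
    two-step technical normalization against PCR and reverse-transcription
    controls, condition-combinatorial analysis plans, 2^-ddCt relative
    quantification with the associated significance conventions, PCA and
    hierarchical-clustering overviews, and a synthetic Ct-data generator
    with known ground truth for validation. Ships the cycle-threshold
    matrix of five candidate reference genes measured in adipose-derived
    mesenchymal stromal cells under serum, inflammatory priming and
    starvation conditions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
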