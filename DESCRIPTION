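Package: discQC
Title: Quality Assessment and Marker-Based Discrimination of Annulus
    Fibrosus and Nucleus Pulposus Disc Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quality sorting of small surgical intervertebral
    disc samples and for molecular discrimination of annulus fibrosus (AF)
    and nucleus pulposus (NP) tissue.  Implements a 12-point tissue-identity
    rubric (IVD score) and a 6-point cellular degeneration rubric (DD
    score) with their decision rules, cohort pass-rate summaries and
    per-donor selection of an expression-profiling cohort; tie-corrected
    Spearman correlation of scoring outcome with donor age and MRI grade;
    an all-pairwise AF-versus-NP chip comparison screen for differentially
    expressed genes (signal log ratios, detection and change call
    frequencies, fold-change consistency) with two-tier marker-candidate
    filters; range-based marker-panel classification of samples of unknown
    tissue origin; efficiency-corrected qPCR relative quantification
    against two reference genes with Mann-Whitney group comparison; and a
    synthetic-data generator with known ground truth so every stage of the
    pipeline can be exercised and benchmarked without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
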