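Package: batbarcode
Title: COI Mini-Barcode Assay Design and Pooled-Sample Species Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for developing and applying DNA mini-barcode assays on
    the mitochondrial COI-5P barcode region, aimed at order-wide species
    identification from degraded, non-invasive samples such as bat guano.
    Provides IUPAC-aware degenerate primer representation with
    weighted-mismatch site scoring, de novo primer design against target and
    exclusion sequence sets, in-silico PCR and per-taxon coverage reports,
    reference-library curation with greedy identity clustering and
    primer-anchored trimming, a bootstrap naive-Bayes k-mer classifier and a
    top-hit identity classifier, a paired-end amplicon read pipeline
    (primer/tail stripping, pair merging, screening, dereplication,
    two-parent chimera flagging, per-species sample profiling), a leave-out
    cross-validation and confidence-threshold evaluation framework, and a
    seeded generator of COI-like reference worlds and pooled read sets with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
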