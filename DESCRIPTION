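Package: fruitmir
Title: Small RNA miRNA Discovery, Target Prediction and Degradome
    Validation for Fruit Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis pipeline for plant
    miRNA discovery, modelled on the workflow used for peach (Prunus persica)
    fruit libraries. Cleans and collapses raw small-RNA reads with full
    read-class accounting, annotates tags against ncRNA/exon/intron/repeat
    features, assigns known miRNAs from miRBase-style databases and builds
    cross-species conservation matrices, predicts novel miRNAs from hairpin
    precursors under nine structural criteria (MIREAP-style), predicts
    targets with the six plant complementarity rules including G:U wobble
    scoring and an MFE-ratio filter, validates cleavage sites from degradome
    (PARE) data, and quantifies relative expression by the 2^-ddCt method.
    Includes a synthetic-data generator that plants hairpins, target sites
    and cleavage peaks with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA (RNAfold, RNAduplex on the PATH)
Config/testthat/edition: 3
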