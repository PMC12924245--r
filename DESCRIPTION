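Package: phagewatch
Title: Prophage Surveillance in Bacterial Genomes from Multi-Detector
    Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Consensus prophage calling from multiple external detector
    outputs, with interval merging, rule-based selection criteria and
    quality gating; synteny-anchor boundary refinement against a
    phage-free reference strain and attL/attR direct-repeat detection;
    keyword-lexicon functional annotation with morphology and
    inducibility rules; VIRIDIC-style intergenomic similarity and ICTV
    threshold clustering of prophage sequences; CRISPR array handling
    with leader-aware orientation, shared spacer blocks, and
    spacer-to-prophage matching under empirical target-decoy false
    discovery rate control; integration-site integrity assessment; and a
    seeded synthetic-fixture generator so the whole pipeline is testable
    without external downloads. Designed around surveillance of
    industrial methanotroph (Methylococcus) cultures, but applicable to
    any bacterial genome set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
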