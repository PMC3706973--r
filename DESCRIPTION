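Package: clppkit
Title: Design and Simulation Toolkit for Complementary Long Padlock Probe Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted resequencing with complementary long padlock
    probes (cLPPs): design of restriction-trimmed probe precursors and
    functional probe duplexes for a target panel, in silico restriction
    digestion, simulation of multiplex capture on synthetic diploid genomes
    with planted variants and copy-number changes, reciprocal paired-end (rPE)
    library amplification and read generation, a read classification and
    processing pipeline (demultiplexing, insert-reference filtering,
    orientation-based PCR-group splitting, amplicon-anchored coverage and a
    pileup genotyper), and read-depth copy-number analysis with scale
    normalization, median combination, lowess smoothing and threshold calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
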