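Package: enchipr
Title: Consolidation of enChIP-Seq Peak Lists from MACS Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to consolidate MACS peak lists from enChIP-Seq
    (engineered DNA-binding molecule-mediated chromatin immunoprecipitation
    followed by sequencing) experiments. Reads MACS tab-delimited peak
    files into tidy peak tables, subtracts peaks found in negative-control
    samples (off-target sites of the CRISPR complex), extracts peaks common
    to multiple on-target gRNA samples, and filters peaks on tag number and
    fold enrichment, including a tag threshold expressed relative to the
    target-locus peak. Includes a seeded synthetic-experiment generator
    with planted ground truth for end-to-end validation, a two-step
    workflow driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    rlang,
    S4Vectors,
    tibble,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
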