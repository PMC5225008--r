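Package: mateSV
Title: Mapping Balanced Translocation Breakpoints from Whole-Genome
    Mate-Pair Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nucleotide-level mapping of apparently balanced
    translocation (ABT) breakpoints from long-insert mate-pair sequencing
    data. Implements discordant read-pair classification and clustering
    into structural-variant predictions, filtering against read support,
    known-variant catalogues and family members, split-alignment
    refinement of junction sequences with microhomology, indel and
    untemplated-insertion characterization, breakpoint annotation against
    gene models, repeat and conserved non-coding element tracks, and
    repair-mechanism classification (NAHR, microhomology-mediated repair,
    non-homologous end joining). Ships a deterministic mate-pair read
    simulator with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    GenomicRanges,
    methods,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
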