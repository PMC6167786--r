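Package: repclonality
Title: Clonality and Repertoire Analysis of RNA-Seq-Derived B/T-Cell
    Receptor Clonotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of B/T-cell receptor (BCR/TCR) clonotype
    tables extracted from bulk RNA sequencing, as produced by MiXCR-style
    aligners. Reads and writes an AIRR-flavoured TSV dialect, translates and
    classifies VDJ junctions as productive or nonproductive, filters
    clonotypes by read support, computes clonal read fractions and CPM,
    classifies per-sample clonality (monoclonal, biallelic/biclonal,
    oligo/polyclonal), clusters somatic-hypermutation subclones, fingerprints
    junctions shared across samples, builds gene-segment usage matrices,
    produces CDR3 multiple alignments, consensus sequences and length
    distributions, and infers neighbor-joining trees from Poisson-corrected
    amino-acid distances. Includes a scenario-controlled synthetic repertoire
    generator with ground-truth labels for recovery testing and a YAML-driven
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
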