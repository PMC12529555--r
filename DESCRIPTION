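Package: vdjgermline
Title: Germline V(D)J Gene Annotation for T-Cell Receptor Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotation of germline T-cell receptor (TR) loci from genome
    sequence: detection and scoring of recombination signal sequences (RSS)
    under the 12/23 rule, construction of V, D, J and C gene models from
    translated homology seeds and RSS evidence, IMGT-style
    functional/pseudogene classification with explicit reason codes, and
    locus-level statistics (gene inventories, F/P ratios, V-intron length
    comparisons with Wilcoxon rank-sum and Fisher exact tests). Includes a
    synthetic-locus generator that plants V/D/J/C segments with configurable
    pseudogene defects and exact truth annotations, so the whole pipeline is
    testable without external data, plus GFF3/FASTA/BED/TSV interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
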