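Package: bsamap
Title: Bulk Segregant Analysis of Pooled Whole-Genome Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mapping-by-sequencing toolkit for bulk segregant analysis (BSA)
    of quantitative traits in biparental crosses. Provides a forward-in-time
    simulator of backcross-derived recombinant inbred populations with
    additive QTL models and pooled short-read sampling, phenotypic tail
    bulking, a variant-calling threshold filter cascade (coverage, supporting
    read count, allele frequency, site quality, multi-allelic and
    non-parental exclusion), a two-step candidate-marker association
    procedure based on chi-square tests of the 1:1 read-count null in both
    bulks, single-linkage clustering of candidates into linkage-drag regions,
    codon-coordinate annotation of CDS substitutions, and a guide-gene
    co-expression screen by (optionally weighted) Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
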