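Package: gliomaPairs
Title: Temporal Genomic Comparison of Paired Primary and Recurrent
    High-Grade Gliomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for paired primary/recurrence tumor exome and
    methylation data, with an emphasis on pediatric high-grade glioma.
    Implements multi-caller somatic variant consensus with a quality, allele
    frequency, matched-normal and population-frequency filter cascade;
    temporal partitioning of variants into shared and private sets with
    molecular-group assignment; detection of allelic imbalance from B-allele
    frequencies; joint coverage plus B-allele-frequency calling of
    amplification, deletion and copy-neutral LOH at segment-union and
    chromosome-arm level; hierarchical clustering of 450K-style methylation
    beta values; and cohort-level clinical summaries with paired tests. A
    synthetic paired-tumor cohort generator with full ground truth makes every
    stage testable without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
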