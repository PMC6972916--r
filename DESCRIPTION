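Package: cfmarrow
Title: Bone Marrow Activity Profiling from Cell-Free mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reading bone-marrow activity out of circulating
    cell-free mRNA sequencing profiles. Implements reference-guided
    cell-type signature construction (fold-change specificity and
    pairwise-enrichment rules), transcriptome deconvolution by
    non-negative matrix factorization with reference-based component
    annotation and by simplex-constrained non-negative least squares,
    longitudinal lineage-trajectory summaries during marrow ablation and
    reconstitution, immunoglobulin clonotype abundance tracking, and
    allograft chimerism monitoring from expressed-SNP allele frequencies.
    A synthetic-data module generates every input type with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    tools,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
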