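Package: isomiRpipe
Title: IsomiR Enumeration, Quantification and Differential Expression for
    Small RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for isomiR-resolved analysis of single-end
    small RNA-seq libraries, built for dietary extracellular-vesicle (EV)
    miRNA transfer studies such as postprandial profiling of calf plasma EVs
    after colostrum feeding. The package enumerates an isomiR mapping
    reference from mature/hairpin miRNA FASTA files (5'/3' trimming and
    templated extension variants), trims 3' adapters, removes
    rRNA/tRNA/snRNA/snoRNA contaminants, assigns reads to isomiR variants
    with an exact/one-mismatch best-stratum matcher producing
    mismatch-annotated isomiR keys, performs negative-binomial differential
    expression with median-of-ratios normalization and conservative
    significance filters, and provides downstream profile analytics (RNA
    species distribution, Ward clustering, top-variance PCA,
    abundance/up-regulation overlap, miRNA target-set pathway enrichment).
    A synthetic-data generator with full per-read ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, miRNA, SmallRNA, DifferentialExpression,
    Transcriptomics, Preprocessing
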