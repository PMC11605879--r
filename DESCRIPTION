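Package: ThanatoSeq
Title: Post-Mortem Time-Course Transcriptome and miRNAome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for post-mortem (thanatotranscriptomic)
    time-course expression studies combining mRNA-seq and miRNA-seq.
    Provides FPKM/TPM normalization with abundance filtering,
    negative-binomial Wald differential expression with
    Benjamini-Hochberg control, fuzzy c-means temporal clustering for
    time-specific gene assignment, dynamical-network-biomarker (DNB)
    tipping-point detection from per-time variance and correlation
    structure, seed-match plus duplex-score miRNA target prediction,
    topological-overlap co-expression modules with exact small-sample
    Spearman filtering, multi-criteria mRNA-miRNA pair integration, and
    hypergeometric over-representation analysis. Includes a synthetic
    count-data generator with planted differential expression,
    time-specific peaks, a DNB module, and seed-complementary miRNA
    target pairs, so the full pipeline is testable against known truth.
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
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
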