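Package: phenoGSEA
Title: Phenotype Molecular Signatures and Exhaustive Pairwise Gene Set
    Enrichment Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts phenotype-specific molecular signatures from normalized
    expression matrices using five differential statistics with
    sample-permutation p-values (never-zero corrected) and
    Benjamini-Hochberg or Benjamini-Yekutieli false discovery rate control,
    then assesses signature enrichment by running the weighted
    Kolmogorov-Smirnov gene set enrichment statistic over every pairwise
    phenotype comparison of an independent dataset.  Permutation nulls are
    pooled across the whole comparison-by-gene-set grid, the false discovery
    rate is controlled map-wide with the Benjamini-Yekutieli procedure, and
    results are rendered as a deterministic bubble-matrix figure in which
    bubble area encodes the normalized enrichment score, color the enriched
    phenotype, and intensity the significance.  Reads and writes the GSEA
    ecosystem file formats (GCT, CLS, GMT, GMX) and ships a synthetic-data
    generator with planted class-specific signature blocks so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
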