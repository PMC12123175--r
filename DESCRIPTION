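Package: asdmtools
Title: Subphenotype-to-Genotype Discovery for Autism with Disproportionate
    Megalencephaly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for linking the disproportionate-megalencephaly
    subphenotype of autism to candidate genes and validating them in a
    zebrafish model. Classifies probands into macrocephaly subtypes (somatic
    overgrowth, disproportionate, relative) from age- and sex-referenced
    growth standards; extracts de novo, rare, likely gene-disruptive variants
    from trio genotypes with a copy-number inclusion rule and burden
    statistics; expands candidate gene sets over a scored interaction network
    with hypergeometric ontology enrichment; compares larval morphometric
    features with rank-sum tests and Bonferroni stars and quantifies
    RT-qPCR knockdown by delta-delta-Ct; and runs a single-cell expression
    stage (QC, normalization, PCA-based hierarchical clustering,
    cluster-proportional downsampling, rank-sum differential expression,
    FMRP-target enrichment and gene-set shift tests). A synthetic-data module
    generates every input format with known ground truth so the full pipeline
    is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
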