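Package: epipair
Title: Knowledge-Driven SNP-SNP Interaction Scanning for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("epipair", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting gene-gene (epistatic) interactions underlying
    quantitative traits such as blood lipid levels. Implements the orthogonal
    Cockerham two-locus coding, covariate-adjusted linear models with and
    without the four interaction components (additive x additive, additive x
    dominance, dominance x additive, dominance x dominance), the 4-degree-of-
    freedom interaction F-test and per-component t-tests, genotype and
    phenotype quality control (call rate, minor allele frequency, exact
    Hardy-Weinberg test, 3x3 genotype cell counts, composite LD r^2),
    knowledge-driven candidate pair generation (GWAS hit lists, gene-pair
    lists, pathway gene sets with flanked SNP-to-gene mapping), an adaptive
    three-stage locus-based validation procedure with sequential stopping and
    per-stage Bonferroni correction, kinship-aware phenotype residualization
    by restricted maximum likelihood, and a fully reproducible synthetic-data
    generator emulating tag-SNP linkage-disequilibrium attenuation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
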