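Package: snp2target
Title: Evidence Integration for Prioritizing Functional Variants at GWAS Risk Loci
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A variant-to-function toolkit for noncoding GWAS loci. Given phased
    haplotypes, a tumor cohort (genotype dosages, gene copy number, expression,
    survival), a GWAS catalog, epigenomic peak sets, chromatin-interaction
    anchors, and transcription-factor position weight matrices, the package
    ranks tag SNPs by pleiotropic GWAS density, runs a copy-number-adjusted
    cis-eQTL scan, tests survival differences by median expression split,
    expands the tag SNP into its high-LD proxy set (D', r-squared from phased
    haplotypes), overlays open-chromatin and interaction-anchor evidence, and
    quantifies allele-specific motif disruption with an exact log-odds score
    p-value and an empirical null-mutation test. A seeded synthetic-data module
    generates all inputs with the statistical structure the analysis assumes, so
    the full pipeline is testable without controlled-access downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
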