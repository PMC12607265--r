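Package: teqhot
Title: Trans-eQTL Hotspot Detection for Gene-Panel Expression GWAS
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping trans-regulatory hotspots from single-marker
    expression GWAS of a gene panel. Provides genotype filtering and recoding,
    vectorised per-gene linear association scans, cis/trans classification by
    genomic distance, three tiers of hotspot detection (hot SNPs, hot top SNPs
    and windowed hotspots), analytic binomial and permutation null models with
    false discovery rates, Z-score pathway expression indices usable as GWAS
    traits, candidate-gene annotation by transcription-start-site distance, and
    a synthetic-data generator with planted cis and trans regulatory
    architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociation, GeneExpression, SNP, Regulation
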