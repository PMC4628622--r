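Package: cosegr
Title: Pedigree-Aware Co-Segregation Filtering of Rare Exome Variants
Version: 0.1.0
Authors@R: person("cosegr", "maintainers", email = "cosegr@example.org",
    role = c("aut", "cre"))
Description: Family-based rare-variant discovery for autosomal-dominant traits.
    Reads per-sample exome variant calls and a multi-generation pedigree,
    scans for variants carried by every affected and no unaffected sequenced
    individual (with read-support thresholding and merging of adjacent
    substitutions into multi-nucleotide variants), applies a rarity /
    consequence / brain-expression filter cascade, overrides exome calls with
    validation genotypes, and issues per-variant co-segregation verdicts on
    the full pedigree under a dominant model with configurable penetrance
    tolerance. Includes a gene-dropping simulator (penetrance, phenocopies,
    genotyping error, in-house cohort database) so every stage is testable
    without external data, plus a packaged worked-example fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
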