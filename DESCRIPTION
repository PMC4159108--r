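Package: mirpopgen
Title: Population Differentiation and Diversity Analysis of miRNA Variants
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for analysing genetic variation in microRNA hairpins
    across human populations. Annotates variants by miRNA region (seed, mature,
    stem-loop), flags novel variants and filters undescribed singletons,
    computes Watterson's theta by sequence class, detects population-specific
    miRNA alleles (PSMAs), estimates pairwise Weir-Cockerham F_ST with
    empirical-percentile outlier calling of population-differentiated miRNAs,
    and runs bootstrap enrichment analyses for target genes, biological
    processes and disease associations. Includes a synthetic-data generator
    (Balding-Nichols genotypes, miRBase-style catalogs, evidence/GO/disease
    tables with planted structure) so the full pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
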