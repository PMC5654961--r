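Package: meqtlkit
Title: Cis-meQTL Screens with Permutation FDR, Matched-Null GWAS Enrichment,
    and Bias-Corrected Functional Follow-Up
Version: 0.1.0
Authors@R:
    person("meqtlkit", "developers", email = "meqtlkit@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating genotype and DNA-methylation data:
    power-driven design of cis methylation quantitative trait locus (meQTL)
    screens, additive-model meQTL discovery with permutation-based false
    discovery rate calibration, enrichment testing of GWAS SNP sets against
    stratum-matched null SNP sets, Gene Ontology analysis of meQTL-target
    CpGs with Wallenius probe-count bias correction and cross-tissue scaled
    ranking, and regulatory-feature overlap testing with Fisher exact
    contrasts. Includes a synthetic-data generator with planted structure
    (LD-blocked genotypes, additive methylation effects, enriched GWAS and
    feature annotations) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
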