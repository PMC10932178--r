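Package: bubalusTwas
Title: Transcriptome-Wide Association Pipeline for Buffalo Milk Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end transcriptome-wide association study (TWAS) workflow
    for milk production traits in water buffalo: random-regression test-day
    model estimation of breeding values with Legendre polynomials and a
    pedigree numerator relationship matrix; genotype quality control (call
    rate, minor allele frequency, exact Hardy-Weinberg test), kinship and
    principal components; TPM normalisation and expression filtering;
    per-gene cis-eQTL weight training by Dirichlet process regression fitted
    with mean-field variational inference and 5-fold cross-validated model
    retention; covariate-adjusted single-SNP association scans; and
    summary-statistic gene-based burden Z tests in the FUSION and SPrediXcan
    forms against an LD reference panel. Includes a seeded synthetic-data
    generator (pedigree, LD-structured genotypes, cis-regulated expression,
    multi-parity test-day records) so the full chain runs and is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    jsonlite,
    Matrix,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
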