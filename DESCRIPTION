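Package: pairgo
Title: Pairwise Epistasis Scans with Permutation Nulls and Gene Ontology
    Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exhaustive pairwise scans of case-control SNP data with the
    multifactor dimensionality reduction (MDR) classifier, genome-wide
    significance via a max-statistic permutation null, window-based
    SNP-to-gene assignment, and a two-level hypergeometric enrichment
    cascade (significant SNPs within genes, significant genes within gene
    sets) with cross-cohort replication. Includes a synthetic-data
    generator that plants purely epistatic penetrance models in known
    genes for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
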