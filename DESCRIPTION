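Package: hybridsex
Title: Sex-Chromosome Linkage and Ancestry Analysis for Hybrid Backcross Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting a ZW sex-linkage system from RAD-seq genotype
    and coverage data and for tracing parental ancestry through long-term
    hybrid backcross pedigrees. Provides a per-SNP exact allelic association
    scan with Bonferroni and suggestive thresholds, windowed Weir-Cockerham
    F_ST between the sexes, median-ratio normalization and dosage-based
    classification of W- and Z-linked loci, sorting of species-diagnostic
    alleles through a backcross pedigree with observed-versus-expected
    segregation tables, detection of retained maternal-ancestry blocks
    (including a translocated sex-determining region), and a stochastic
    neutral backcross-drift null model for testing excess ancestry retention.
    A synthetic-data module simulates parental strains, crosses and RAD-style
    coverage with known ground truth so the whole pipeline runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
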