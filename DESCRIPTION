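Package: jostscan
Title: Jost's D Genome Scans, Population Structure and Mixed-Model GWAS for
    Diverse SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic analysis of diverse biallelic SNP
    genotype panels such as maize inbred collections: panel merging with
    complementary-strand allele reconciliation, MAF and missingness screening,
    gene diversity, polymorphism information content, heterozygosity,
    identity-by-state distance and centered-IBS kinship, linkage-disequilibrium
    decay profiling, Patterson-normalised principal component analysis with a
    marker-subsampling sufficiency curve, neighbor-joining cluster extraction,
    windowed Jost's D genome scans with region calling and QTL-interval
    overlap, and mixed linear model association mapping with Bonferroni
    thresholding. A Balding-Nichols genotype simulator with plantable
    differentiated regions and quantitative trait nucleotides provides
    ground-truth panels for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
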