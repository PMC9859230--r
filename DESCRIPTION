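Package: popgenchip
Title: Population-Genetic Analysis of Livestock SNP-Chip Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for diploid autosomal SNP-array data from
    livestock populations: marker and sample quality control with an exact
    Hardy-Weinberg test, minor-allele-frequency spectra, pairwise linkage
    disequilibrium (r2) via EM haplotype-frequency estimation for unphased
    genotypes, binned LD-decay curves, LD-based historical effective
    population size under the Sved relation with a Haldane map correction,
    the VanRaden genomic relationship matrix with PCA and mean genomic
    kinship, and single-trait genomic REML heritability by eigendecomposition
    of the relationship matrix. A seeded Wright-Fisher forward simulator with
    recombination and piecewise-constant population size generates synthetic
    genotype and phenotype data with known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
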