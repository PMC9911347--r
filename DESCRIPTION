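Package: popkin
Title: Population-Genetic Analysis of Ancient DNA Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical analyses used in ancient-DNA population
    studies of pseudo-haploid 1240K-style genotype data: EIGENSTRAT input and
    output, f-statistics (f2, f3, f4) with weighted block-jackknife standard
    errors, qpWave rank tests and qpAdm admixture-coefficient estimation,
    admixture dating from the exponential decay of ancestry covariance with
    genetic distance, pairwise-mismatch (READ-style) and maximum-likelihood
    IBD kinship inference with constraint-based pedigree reconstruction, and
    a runs-of-homozygosity HMM with pedigree-simulation-based consanguinity
    classification. Includes a seeded synthetic-data generator (drifted
    populations, admixture tract mosaics, pedigrees with recombination,
    pseudo-haploid downsampling) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
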