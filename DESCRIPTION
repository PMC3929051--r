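Package: breedscan
Title: Selection Signatures and Population Structure in Livestock SNP Panels
Version: 0.1.0
Authors@R:
    person("breedscan", "developers", , "devel@breedscan.org", role = c("aut", "cre"))
Description: Tools for genome scans of divergent selection and population
    structure in multi-breed SNP chip panels. Reads PLINK text genotypes,
    applies a two-pass quality-control cascade (call rate, minor allele
    frequency, heterozygosity outliers, per-breed Hardy-Weinberg exact
    tests), computes per-locus multi-population fixation indices with the
    Nei-Chesser sample-size-corrected estimator, averages them in SNP
    windows and calls empirical-quantile outlier regions (including
    one-breed-versus-rest contrasts), estimates genomic kinship and
    classical multidimensional-scaling embeddings with per-breed cluster
    geometry, and fits the admixture model by Gibbs sampling with a
    multi-run harness and the Evanno delta-K model-choice statistic. A
    built-in Balding-Nichols simulator generates chip-style panels with
    drifted breeds, selected loci, missingness and Hardy-Weinberg
    violations so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
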