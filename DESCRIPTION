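Package: ld3
Title: Third-Order Linkage Disequilibrium for Biallelic SNPs
Version: 0.1.0
Authors@R:
    person("Torbiscal", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation, generation and dynamics of third-order (three-locus)
    linkage disequilibrium for biallelic SNPs. Provides the canonical
    decomposition of three-locus haplotype frequencies into allele
    frequencies, pairwise and third-order disequilibrium coefficients;
    admissible-range bounds and Robinson-style normalization; an
    expectation-maximization estimator of the eight haplotype frequencies
    from unphased diploid genotypes with a likelihood-ratio test against
    the independence model; a two-population admixture model that generates
    third-order disequilibrium; the deterministic recombination recursion
    for its break-up over generations; genome-scan drivers over SNP
    triplets (consecutive, inter-chromosomal, rolling window); and a
    seeded synthetic-genotype generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
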