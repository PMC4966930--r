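Package: icskin
Title: Pairwise Kinship Analysis from High-Density SNP Genotypes by
    Chromosome Sharing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forensic pairwise kinship analysis based on the index of
    chromosome sharing (ICS): the summed genetic length (cM) of
    identity-by-state segments longer than a calibrated threshold between
    two individuals genotyped at high-density autosomal SNPs. Provides
    IBS segment detection over a genetic map, an LD-structured synthetic
    founder-haplotype generator, gene-dropping pedigree simulation with
    recombination, ROC/AUC threshold calibration, per-relationship
    distribution fitting (normal, truncated-normal, log-normal) with AIC
    model selection, and probabilistic evaluation of relationships via
    likelihood ratios and flat-prior Bayesian posteriors mapped to
    Hummel's verbal predicates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
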