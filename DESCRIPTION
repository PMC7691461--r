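Package: popdivscan
Title: Coalescent Simulation, Joint-SFS Demographic Inference and Genome
    Scans for Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genomic differentiation among structured
    populations connected by migration. Provides a structured-coalescent
    simulator for multi-population isolation-with-migration demographies
    (population splits, asymmetric migration, piecewise-constant sizes,
    optional bottlenecks and an outgroup lineage), Monte-Carlo expected
    joint site-frequency spectra, composite-likelihood demographic
    inference with AIC/Akaike-weight model comparison and parametric
    bootstrap, 10-kb windowed statistics (pi, Watterson's theta, expected
    heterozygosity, Tajima's D, Fay and Wu's H, Fu and Li's D, FST, dxy,
    RND, LD r-squared, rho, PBS), simulation-null outlier testing with
    Benjamini-Hochberg FDR, and HKA/PBS tests for positively selected
    genes. Includes VCF input/output, site filtering, outgroup
    polarization and a reproducible staged pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
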