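Package: sweepscan
Title: Resampling-Based Genome Scans for Selective Sweeps from Allele
    Frequency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects candidate selective-sweep regions from matched
    allele-frequency panels of two or more diploid populations. Computes
    mean heterozygosity, mean F_ST and the multi-locus F_ST variance in
    sliding windows of incrementally increasing sizes centered on every
    SNP, ranks each observed window against a resampled null distribution
    built by unrestricted random sampling of loci, reports the most
    extreme tail percentile per locus across window sizes on a -log10
    scale, and classifies loci into old/new selection patterns. Includes
    a genotype-count converter, a frequency-level two-population
    simulator with injectable sweep signatures, and a permutation test
    for enrichment of selection signals in candidate gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
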