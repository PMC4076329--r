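Package: finemapld
Title: Trans-Ethnic Fine-Mapping of GWAS Loci by LD-Cluster Partitioning and
    Proxy-Set Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Systematic statistical fine-mapping of an associated GWAS locus
    across ancestry groups. Partitions associated variants into linkage
    disequilibrium (LD) clusters around index SNPs, screens clusters by
    pairwise conditional regression and EM-phased haplotype-dosage
    association, combines panels by inverse-variance fixed-effect
    meta-analysis with Cochran's Q heterogeneity testing, and filters
    candidate causal variants by intersecting cross-population proxy sets.
    Includes a synthetic multi-population genotype generator with planted
    haplotype architecture and phenotype effects for validating every
    pipeline stage, plus readers and writers for VCF, PLINK-style text and
    summary-statistic tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
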