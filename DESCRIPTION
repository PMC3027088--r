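Package: jointgwas
Title: Two-Stage Joint SNP and Copy-Number Association Scans in Family Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association analysis of quantitative traits in
    sibship-structured cohorts where each locus carries a CNV-aware genotype:
    counts of the two SNP alleles on however many genomic copies are present.
    Implements the joint two-degree-of-freedom test of an additive allelic
    effect and an additive copy-number effect, fitted genome-wide with a
    two-stage mixed-model procedure: a fast GRAMMAR residual screen over all
    markers, followed by a full family random-intercept REML refit of the
    top-ranked markers. Includes a pedigree-structured data simulator
    (sibships, two-population admixture, rare copy-number alleles), genotype
    principal-component stratification adjustment, genomic-inflation and
    quantile-quantile diagnostics, and TSV readers and writers for the
    genotype, roster and phenotype tables the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
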