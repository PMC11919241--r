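Package: recprev
Title: Recessive Disease Prevalence Estimation from Population Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the prevalence of autosomal recessive disease from
    allele counts observed in population genetic databases such as gnomAD.
    Provides tools to read, normalize and merge curated pathogenic-variant
    catalogs keyed by HGVS coding notation; to triage variants of uncertain
    significance with a minor-allele-frequency filter, CADD score cutoffs
    derived from normal fits to known pathogenic and benign score
    distributions, and a consensus vote over in-silico predictors; to
    compute Hardy-Weinberg and beta-binomial Bayesian prevalence estimates
    with parametric-bootstrap confidence intervals; and to adjust estimates
    with a genotype-compatibility matrix that excludes embryonic-lethal
    (two loss-of-function alleles) and non-penetrant (mild or synonymous
    homozygous) genotype combinations. Includes a seeded simulator of
    gnomAD-like catalogs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
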