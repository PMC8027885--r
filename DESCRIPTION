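Package: stratsim
Title: Simulated-Trait GWAS and Fine-Scale Population Structure in Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates admixed, geographically structured genotype cohorts
    (three ancestral components, group-specific drift, sex-biased
    contributions, local-ancestry tracts) under a two-layer Balding-Nichols
    model, and implements the population-genetic statistics needed to study
    how fine-scale structure confounds case-control association studies:
    Weir-Cockerham FST, UPGMA trees, genotype PCA, Mantel and Procrustes
    tests against geography, Weiszfeld geometric medians, supervised
    ancestry-proportion estimation, X-versus-autosome sex-bias ratios,
    the population branch statistic, local-ancestry enrichment scans,
    allele-frequency fold-change scans, and a simulated-trait GWAS suite
    with genomic-control and principal-component correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    geosphere,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
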