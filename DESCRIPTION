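Package: ecogwas
Title: Environmental and Phenotypic GWAS for Structured Landrace Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting local adaptation in crop landrace panels
    genotyped by reduced-representation sequencing. Covers read-depth
    genotype calling with a threshold-rule caller and filtering cascade,
    population structure (standardized relationship matrix, PCA,
    allele-sharing distances, neighbour-joining trees, cluster assignment
    with an admixed class), differentiation and diversity statistics
    (Weir-Cockerham Fst, Watterson's theta, Pst with bootstrap intervals),
    linkage-disequilibrium decay and block delimitation, photoperiod
    modelling (day length and maximum day length over a growing window),
    an iterative fixed/random-model association scan for phenotypic and
    bioclimatic traits, effect and variance-explained quantification with
    GRM-REML heritability, and classification of selection signals during
    domestication and landrace diversification. A seeded synthetic-panel
    generator reproduces the statistical structure the analyses assume, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
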