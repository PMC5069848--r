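Package: depthcline
Title: Genotype-Phenotype Divergence Along a Water-Depth Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for population-genetic and quantitative-trait
    divergence of fish sampled along a water-depth gradient. Provides
    microsatellite diversity statistics (rarefied allelic richness, private
    allelic richness, unbiased heterozygosity, Fis permutation tests with
    SGoF multiple-testing correction), differentiation statistics
    (Weir-Cockerham theta with permutation and locus-bootstrap inference,
    Jost's D), hierarchical AMOVA factor ranking, Mantel tests for
    isolation-by-depth and isolation-by-distance, principal coordinates
    ordination of individual genotypes, trait preprocessing (percent
    buoyancy, allometric size adjustment by studentized residuals), one-way
    ANOVA with Fisher's LSD, within-group variance profiles, and Pst-Fst
    comparison via both variance components and a Relethford-Blangero style
    R-matrix with Mahalanobis D2 distances. A Balding-Nichols synthetic-data
    generator with known ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
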