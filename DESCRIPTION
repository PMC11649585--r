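Package: genoscaper
Title: Landscape Genomics and Seed Transfer Zone Delineation for Desert Annuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reusable landscape-genomics pipeline for
    reduced-representation SNP data: VCF quality filtering and diversity
    statistics (Weir-Cockerham theta, AMOVA Phi-ST), k-means/BIC and
    discriminant-analysis population structure, habitat-resistance distances
    (least-cost and commute) from a species distribution model, Mantel and
    partial-Mantel causal modeling of isolation by distance, resistance and
    environment, redundancy-analysis genome scans for environmentally
    associated loci, generalized dissimilarity modeling with monotone
    I-splines, gradient-forest-style cumulative turnover functions, genomic
    offset under future climate, and a weighted least-cost nearest-neighbor
    algorithm delineating seed transfer zones. Includes a synthetic-landscape
    generator with planted adaptive clines and known neutral structure so
    every stage can be validated against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    igraph,
    jsonlite,
    MASS,
    Matrix,
    mclust,
    methods,
    pracma,
    rpart,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
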