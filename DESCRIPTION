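Package: rootph
Title: Persistent Homology Phenotyping of 3D Root System Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies 3D root system architecture from voxelized root
    volumes with persistent homology. Builds 26-connected voxel networks,
    assigns geodesic and depth filtration functions, computes H0
    superlevel-set persistence barcodes, bottleneck distances and combined
    population distance matrices, and derives topological trait vectors
    (G_PCs, GH_PCs, PDD_PCs) via multidimensional scaling, principal
    component analysis and Gaussian kernel density vectorization of
    persistence diagrams. Downstream tools cover variance-inflation-factor
    trait pruning with a log-curve threshold rule, multivariate principal
    component traits, broad-sense heritability, allele effect sizes and
    QTL co-localization within genomic windows. Includes a synthetic root
    generator with known ground truth and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
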