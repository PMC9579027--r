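Package: tailbud
Title: Registration, Composite Expression Maps and Criticality Statistics
    for the Zebrafish Tailbud
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the neuromesodermal progenitor (NMp) state
    transition in the zebrafish tailbud from segmented imaging data and
    single-cell counts. Provides rigid point-cloud registration of
    stage-matched tailbud samples (RANSAC coarse alignment followed by
    point-to-plane or colored ICP refinement), k-nearest-neighbour
    imputation of gene-expression channels onto a target cloud to build
    multi-gene composite maps, identification of in-silico NMps and NMp
    probability maps, the correlation-weighted neural-mesodermal (NM)
    index with congruent/compliant/rebellious classification, a
    criticality suite (critical transition index with cluster-balanced
    bootstrap, pairwise-distance transcriptional noise over highly
    variable genes, MAD-based quality control), and a family of discrete
    Shannon entropy estimators (maximum likelihood, Miller-Madow,
    Dirichlet pseudocount, James-Stein shrinkage) with jackknife standard
    errors. Synthetic generators for tailbud-shaped point clouds,
    clustered negative-binomial expression matrices and staged transition
    series support validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, SingleCell, Spatial, Transcriptomics
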