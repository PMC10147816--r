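Package: dogconn
Title: Resting-State Functional Connectome Analysis of the Dog Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline from denoised region-of-interest
    (ROI) BOLD time series to a thresholded weighted brain graph and its
    topology. First-level connectivity is estimated by symmetrized
    semi-partial correlation, Fisher z-transformed, and thresholded at the
    group level with per-edge t-tests combined with a per-seed sign-flip
    omnibus test under Benjamini-Hochberg FDR control. The surviving graph
    is characterised by density, triangle count, small-world scalars against
    degree-preserving rewired null models, two-layer consensus modularity
    community structure with a lateralized-module split, bilateral homolog
    symmetry statistics, bilateral-averaged hub rankings, and Jaccard
    comparison of network-to-ROI parcellations. A synthetic-cohort generator
    with planted modules, bilateral homolog coupling, hub nodes and AR(1)
    noise provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
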