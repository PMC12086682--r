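Package: mdmflow
Title: Multimodal Diffusion Maps for Developmental Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Diffusion-based analysis and visualization of developmental
    multimodal single-cell data. Computes cell-specific modality weights from
    empirical cumulative distribution functions of cross-modality
    nearest-neighbor distances, merges per-modality affinity kernels into a
    weighted multimodal Markov chain, and eigendecomposes it into a multimodal
    diffusion map (MDM) embedding. Includes transition-aware layout-graph
    construction for force-directed visualization, eigenbasis diffusion
    imputation of sparse feature counts, topic-model latent modalities for
    unimodal data, simulated developmental benchmark datasets, and
    embedding-quality scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RANN,
    RSpectra,
    igraph,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    rhdf5,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
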