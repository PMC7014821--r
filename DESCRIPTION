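Package: shardvox
Title: Voxel-Wise SHARD Decomposition and Rank-1 Testing for Multi-Shell
    Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests the single-convolution assumption of white-matter
    diffusion MRI models voxel by voxel.  Multi-shell signals are fitted in
    the even spherical-harmonic basis per shell, arranged into per-order
    shell-by-coefficient matrices and decomposed by singular value
    decomposition (the voxel-wise SHARD decomposition); the signal power
    beyond the leading rank-1 component is quantified and its significance
    assessed with a leverage-corrected residual-bootstrap permutation test
    and Benjamini-Hochberg false discovery rate control across voxel maps.
    Includes a standard-model (stick plus zeppelin) multi-fascicle signal
    simulator, gradient-table and NIfTI-1 input/output, and detectability
    power-surface sweeps for crossing-fibre configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    pracma,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
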