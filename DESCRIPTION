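Package: picotract
Title: Probabilistic Tractography Connectivity Profiling on Synthetic Fibre Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for probabilistic diffusion-MRI tractography
    and seed-to-target connectivity profiling. Provides digital fibre phantoms
    (multi-tensor forward simulation with Rician noise), constrained spherical
    deconvolution (CSD) of fibre orientation distributions, Monte-Carlo
    streamline tracking in the PICo style with per-voxel visitation counting,
    seed-ROI by target-region maximum-connectivity matrices, and a two-level
    group inference combining a per-participant Poisson threshold with
    strict/relaxed group-consistency criteria. All stages run end-to-end on
    synthetic cohorts with known ground-truth connections, so recovery of
    designed connectivity profiles can be tested without any acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
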