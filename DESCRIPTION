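Package: protonCT
Title: List-Mode Proton CT Reconstruction with a Noise-Based Stopping
    Criterion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Least-squares iterative reconstruction of relative stopping
    power (RSP) maps from list-mode proton CT data.  Each proton
    contributes a measured water-equivalent path length (WEPL) and a
    trajectory; the solver iterates along the chord-weighted voxel
    deviation vector with an exact line search and stops when the
    remaining distance to the least-squares solution, expressed relative
    to the estimated voxel noise (the statistic r), falls below a chosen
    threshold.  Includes a synthetic list-mode proton simulator with
    voxelized phantoms, a sparse chord-length system-matrix builder, and
    image-noise analysis tools: region-of-interest variance, per-axis
    voxel autocorrelation functions, the noise power spectrum via the
    Wiener-Khinchin relation, and water-equivalent-thickness line sums.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    data.table,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
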