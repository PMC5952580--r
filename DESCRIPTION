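Package: sbtomo
Title: Split Bregman Total-Variation Reconstruction for Limited-Data Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matrix-free iterative reconstruction for fan-beam and cone-beam
    computed tomography from few projections and/or a limited angular span.
    Implements the Split Bregman formulation of total-variation constrained
    reconstruction with a BiCGStab inner solver, ray-driven (Siddon) forward
    projection and voxel-driven backprojection with chunked memory
    partitioning, a Feldkamp-Davis-Kress filtered-backprojection baseline,
    a synthetic phantom and acquisition simulator, and RMSE/SNR image-quality
    metrics. Volumes are read and written as MetaImage or NIfTI, projection
    stacks as multi-page TIFF with a YAML geometry sidecar.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    tiff,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
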