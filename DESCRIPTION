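Package: megorient
Title: Cortical Column Orientation Models for MEG Source Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes cortical-column dipole-orientation fields from paired
    pial/white-matter cortical surface meshes using five estimators
    (downsampled surface normals, cortical patch statistics, original surface
    normals, link vectors, and a variational vector field), and quantifies how
    orientation and source-location choices affect MEG source inversion.
    Provides correspondence-preserving mesh decimation, an analytic
    spherical-conductor forward model, patch-source simulation at controlled
    per-trial SNR, empirical Bayesian beamformer inversion with ReML
    hyperparameter optimisation and variational free-energy scoring, and
    random-effects family-level Bayesian model comparison via exceedance
    probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
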