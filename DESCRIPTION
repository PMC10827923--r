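Package: gpmorph
Title: Gaussian-Process Morphable Models of Shape and Albedo from a Single Template
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and analysis of 3D morphable models of mesh shape
    and per-vertex albedo from a single vertex-colored template, using
    analytically defined Gaussian-process covariance kernels instead of
    PCA on scan collections. Provides radial-basis matrix-valued kernels
    with bilateral symmetry and colour-channel correlation, Nystrom
    low-rank decomposition into PCA-compatible eigenbases, mixture
    (kernel-density) models over multiple templates, a spherical-harmonics
    Lambertian renderer with Metropolis-Hastings inverse rendering,
    model-based nonrigid registration of scans, an unsupervised
    wake-sleep learning loop from 2D images, and the standard
    specificity, generalization and compactness model-quality measures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
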