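Package: cortlam
Title: Cortical Layer-Complex and Area Segmentation from High-Resolution
    Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic, observer-independent segmentation of cortical
    layer-complexes and architectural area boundaries from high angular
    resolution diffusion MRI. Cortical depth is sampled by solving
    Laplace's equation between the white/gray-matter and pial boundaries
    and integrating streamlines of its gradient field. Apparent diffusion
    coefficient (ADC) profiles are fitted with an even-order spherical
    harmonic basis in a local cortical coordinate frame, yielding total,
    radial and tangential diffusivity summaries plus harmonic
    coefficients. Layer-complexes are found by restarted k-means
    clustering with silhouette-guided model selection; area boundaries by
    multi-scale sliding-block Mahalanobis distances with Hotelling T2
    significance testing and standard-deviation count thresholding. A
    synthetic laminar cortical phantom (folded ribbon, bi-tensor signal,
    Rician noise) supports end-to-end testing, and validation utilities
    provide contingency cross-tables, chi-squared statistics, label
    downsampling, profile correlations and SNR measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
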