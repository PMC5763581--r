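Package: respfit
Title: Unified Image Registration and Surrogate-Driven Respiratory Motion
    Modelling from Full and Partial Image Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits surrogate-driven respiratory correspondence models directly to
    dynamic image data by unifying deformable B-spline registration and model
    fitting into a single gradient-based optimisation. Supports 'partial' image
    data (slabs, thin slices, thick Gaussian-profile slices) through image
    acquisition operators and their adjoints, and incorporates motion-compensated
    image reconstruction (weighted averaging and iterative back-projection
    super-resolution) in an alternating scheme, so that both the motion model and
    a motion-free reference image can be estimated from partial data alone.
    Includes a seeded 2D lung-like phantom simulator with known ground-truth
    motion for quantitative validation, and displacement-field-error, image
    agreement and snap-to-voxel landmark evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
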