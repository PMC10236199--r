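Package: morphforge
Title: Landmark-Free Personalization of Finite-Element Body Models by
    Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Morphs a baseline finite-element human body model onto a target
    subject without landmarks. Skin and skeleton surfaces of both bodies are
    voxelized into three-label images (background 0, flesh 1, skeleton 2),
    a dense displacement field is estimated with a diffeomorphic Demons
    registration (baseline fixed, subject moving), and baseline mesh nodes
    are moved through the interpolated field while element connectivity,
    part IDs and contact definitions are preserved. Personalization accuracy
    is quantified with the DICE overlap and the 95th-percentile Hausdorff
    distance, and mesh health with scaled Jacobian, aspect ratio, minimum
    edge length and contact-intersection checks. Includes pipeline variants
    with global pre-scaling and regional shielding, readers and writers for
    STL, legacy VTK, an LS-DYNA keyword subset, NIfTI and MetaImage, and a
    parametric phantom generator with analytic ground-truth deformations for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
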