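Package: foliaflat
Title: Surface Reconstruction, Inflation and Flattening of Folded
    Cortical Sheets from Two-Echo MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct thin, doubly folded cortical sheets
    (such as the cerebellar cortex) from paired short-TE proton-density
    and long-TE T2*-weighted MRI volumes. Provides synthetic folded-sheet
    phantoms with exactly known surface area, echo combination and bias
    flattening, structure-tensor oriented anisotropic smoothing,
    white-matter segmentation and voxel-face tessellation, deformable
    refinement into gray/white and pial surfaces, geometry-preserving
    inflation with dual-scale folding maps (local curvature and average
    convexity), cutting and metric-distortion-minimizing flattening,
    fixation-shrinkage-corrected area reports, and a voxel-size
    resolution-loss analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
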