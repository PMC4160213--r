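Package: wallfibril3d
Title: Quantitative Analysis of Fibril Networks in Cell-Wall Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the fibrillar architecture of plant primary
    cell walls in electron tomograms. Provides a synthetic phantom generator for
    layered microfibril networks with known geometry and realistic imaging
    corruption (point-spread blur, missing wedge, noise), nonlinear anisotropic
    diffusion denoising, structure-tensor orientation analysis, threshold and
    contour-spectrum segmentation, topology-preserving 3D skeletonization with
    fibril/cross-link classification, cross-sectional metrology (microfibril
    diameter, edge-to-edge and center-to-center spacing, cross-link length), and
    notched-boxplot group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
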