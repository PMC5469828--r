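Package: thglcn
Title: Lacuno-Canalicular Network Analysis for Label-Free Third-Harmonic
    Generation Bone Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the bone lacuno-canalicular network
    (LCN) from third-harmonic generation (THG), second-harmonic generation
    (SHG) and fluorescence microscopy stacks. Provides synthetic multimodal
    bone phantoms with exhaustive ground truth, empirical point-spread
    function estimation from sub-resolution canalicular cross-sections,
    Richardson-Lucy deconvolution, multiscale Hessian (Frangi) vesselness
    enhancement, topology-preserving 3D skeletonization, lacuna
    segmentation, canalicular diameter and porosity quantification,
    signal-to-background and lamellar-period measurements, and bone
    structural unit (BSU) segmentation from cement-line contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
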