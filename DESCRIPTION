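Package: vbmsparing
Title: Voxel-Based Morphometry of Treatment-Induced Gray-Matter Sparing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the voxel-based morphometry
    workflow used to localize treatment-induced gray-matter sparing in a
    two-arm longitudinal trial: synthetic longitudinal modulated GM-map
    cohorts with known effect geometry, Gaussian smoothing and lesion
    in-painting, a mass-univariate group-by-time general linear model with
    subject and site nuisance terms, Benjamini-Hochberg FDR control with 3D
    cluster extraction, a clinical disability-specific atlas from voxelwise
    GM-score partial correlation, the spatial overlap of the two regions,
    and downstream region-volume and clinical correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    pheatmap,
    withr,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
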