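Package: osteovox
Title: Phantom-Based Validation of 2D and 3D Morphometry of Cortical
    Bone Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates voxelised in silico phantoms of intracortical bone
    microstructure (vascular canals as elliptic cylinders, osteocyte
    lacunae as prolate spheroids) with known ground truth, estimates canal
    orientation and lacunar volume with section-based (2D) and volumetric
    (3D) methods, classifies canal orientations into longitudinal, radial
    and laminar categories, and quantifies method agreement with Pearson
    r-squared, Bland-Altman limits and classification accuracy. Includes
    supersampled partial-volume voxelisation, minimum cross-entropy (Li)
    thresholding, 3D topology-preserving skeletonisation with branch
    analysis, and moment-based ellipse and ellipsoid fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
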