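Package: ctlungseg
Title: Automatic CT Lung Segmentation and 3D Surface Reconstruction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fully automatic segmentation of the lungs from thoracic computed
    tomography (CT) volumes in Hounsfield units, and reconstruction of the
    result as a smoothed, decimated triangle mesh. Implements the classical
    staged approach: Hounsfield-unit thresholding, three-dimensional binary
    morphology with spherical structuring elements (exact Euclidean
    distance-transform based erosion and dilation), iterative voting hole
    filling, connected-component labelmap analysis with geometric removal
    rules (small groups, border-spanning groups, thin stretcher structures),
    mask refinement, and a voxel-level vessel/parenchyma split. Includes
    readers and writers for single-frame CT DICOM series, NRRD and MetaImage
    (MHA) volumes, OBJ/STL mesh export, per-slice PNG overlay rendering, a
    synthetic thoracic CT phantom generator with voxel-exact ground truth for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
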