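Package: mracad
Title: Computer-Assisted Detection of Cerebral Aneurysms in TOF-MRA Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end computer-assisted detection (CAD) pipeline for
    cerebral aneurysms in time-of-flight magnetic resonance angiography
    (TOF-MRA). Step one segments the arterial tree fully automatically
    (bias-field correction, histogram normalization, sigmoid vessel
    enhancement, bounding-box skull stripping, auto-threshold region growing,
    marching-tetrahedra surface meshing, spherical volume-of-interest
    dilation). Step two detects aneurysms per voxel with a compact 3D U-Net
    featuring a context aggregation pathway and deep supervision, converts
    predicted components into sphere markers, and evaluates detections with
    the sensitivity / false-positives-per-case protocol standard in lesion
    CAD. A seeded synthetic vascular phantom generator provides ground truth
    for every stage.
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
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
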