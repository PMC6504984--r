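Package: meshfidelity
Title: Fidelity of Threshold-Segmented CBCT Surface Meshes Against a
    Reference Scan
Version: 0.1.0
Authors@R:
    person("meshfidelity", "developers", role = c("aut", "cre"),
           email = "meshfidelity@example.org")
Description: Quantifies how accurately triangular meshes segmented from
    cone-beam CT (CBCT) voxel data reproduce a reference-scanned dental
    stone model. Provides a synthetic CBCT phantom generator (parametric
    dental arch, partial-volume voxelization, device blur/noise/HU
    calibration), DICOM series and STL input/output, iso-surface mesh
    extraction across a Hounsfield-unit threshold sweep, two-stage rigid
    registration (Kabsch point fit plus iterative closest point on
    sampled surface pairs), surface deviation statistics including the
    Dissimilarity Index (median times interquartile range times 1000),
    best-threshold selection, and repeated-measures ANOVA with
    Greenhouse-Geisser correction and Dunn-Sidak corrected pairwise
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
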