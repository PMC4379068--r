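Package: bregma
Title: Tracer-Specific Rat Brain Templates, Registration Validation and
    Voxel-Based Analysis for Small-Animal PET/SPECT
Version: 0.1.0
Authors@R: person("bregma", "maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Construction of symmetric, tracer-specific small-animal brain
    templates in bregma-centered stereotaxic (Paxinos) space from PET and
    SPECT standardized-uptake-value volumes; intensity-based spatial
    normalization (sum-of-squared-differences affine and normalized-mutual-
    information rigid registration); quantitative validation of registration
    accuracy by a randomized-misalignment protocol; volume-of-interest
    uptake statistics with right-to-left asymmetry ratios; and voxel-based
    two-sample group comparison with permutation-based cluster-level
    family-wise-error control and glass-brain projections.  Includes a
    digital rat-brain phantom generator so the full pipeline is exercisable
    without scanner data, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
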