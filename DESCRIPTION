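Package: mowtract
Title: Multi-Fiber Tractography by Mixture-of-Wisharts Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-voxel fiber-orientation estimation for diffusion-weighted
    MRI by mixture-of-Wisharts spherical deconvolution with non-negative
    least squares, displacement-probability evaluation on an icosphere,
    multi-start peak extraction, dense-seed deterministic streamline
    tractography with a turn-angle stopping rule, ROI-based connectivity
    filtering, and track-volume statistics.  Includes a multi-tensor DWI
    phantom simulator with Rician noise so the whole pipeline can be
    validated against known fiber geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    pracma,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
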