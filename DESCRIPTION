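Package: ttdose
Title: Tumor Treating Fields Dosimetry with Skull-Remodeling Burr Holes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for studying how skull-remodeling burr holes
    and transducer-array placement shape the intracranial dose of tumor
    treating fields (TTFields). Builds a synthetic layered head phantom with a
    resection cavity, residual tumor and a five-hole burr-hole quincunx,
    solves the quasi-static ohmic conduction problem on the voxel grid with a
    conservative finite-volume discretization, and computes dose-volume
    statistics, field-enhancement maps relative to a no-hole control, and
    Monte-Carlo uncertainty estimates for the burr-hole conductivity.
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
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
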