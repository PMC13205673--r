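Package: ctmigsim
Title: Synthetic Implant Migration Simulation for CT-Based Migration Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic follow-up CT volumes from a single baseline
    hip CT with a femoral stem implant by translating the implant voxels in
    integer-voxel steps within a stem-aligned coordinate frame, keeping the
    surrounding anatomy untouched. The applied voxel shifts times the voxel
    spacing define exact ground-truth migrations, enabling controlled
    validation of CT-based migration measurement (CT-RSA) tools. Includes a
    digital hip phantom generator, the one- and two-axis shift protocol
    enumeration, a transparent threshold/centroid measurement stand-in, and
    the accuracy/precision evaluation layer (per-axis difference summaries,
    zero-migration precision as 1.96 x SD, Bland-Altman limits of agreement,
    and Q-Q normality data).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
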