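Package: applicatr
Title: Patient-Specific Brachytherapy Applicator Design and Needle
    Insertion-Force Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Design pipeline for personalised gynaecological brachytherapy
    applicators derived from segmented MRI contours: import of DICOM
    RT-structure contours (or an equivalent plain-text dialect), binary
    labelmap rasterisation and watertight surface reconstruction with
    shrink-resistant Taubin smoothing, curvature-constrained planning of
    curved needle channels, voxel-boolean carving of swept channels with
    tapered interstitial tips and fillable reconstruction loops, STL
    export, and generation of the curved-channel calibration template.
    Includes the companion needle insertion-force analysis (zero-phase
    moving-average filtering, per-insertion summaries, buckling
    detection, two-way ANOVA with Tukey-Kramer post-hoc comparisons) and
    synthetic fixture generators for vault-like contour stacks, channel
    waypoints, and force-depth traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
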