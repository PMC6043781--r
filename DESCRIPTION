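Package: seegloc
Title: SEEG Depth-Electrode Contact Localization, Atlas Labeling and Cohort Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for stereoelectroencephalography (SEEG) implantation
    analysis: parametric depth-electrode models placed along two-point trajectories
    in volumetric head images, per-contact anatomical labeling by sphere majority
    vote against atlas and tissue volumes, resection-mask computation from pre- and
    post-operative brain masks with per-parcel overlap quantification, a
    multi-criteria patient cohort store, and group-level parcellation quality
    control with robust outlier statistics (4xMAD rule and the Chauvenet
    criterion). Includes deterministic synthetic-fixture generators so the whole
    pipeline runs with zero clinical data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
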