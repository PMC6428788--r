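Package: cartoplan
Title: MRI-Based Treatment Planning and Accuracy Evaluation for
    Image-Guided Intramyocardial Injection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans catheter-based intramyocardial injection therapy from
    segmented late gadolinium enhancement (LGE) cardiac MRI. Segments the
    infarct with the full-width-at-half-maximum rule, projects infarct
    transmurality and wall thickness onto an endocardial surface mesh,
    places injection targets in the infarct border zone (1-20 percent
    transmurality, wall thickness over 5 mm) while flagging danger zones,
    registers the plan rigidly to an interventional epicardial point cloud
    with a two-stage (principal-axes then trimmed iterative closest point)
    procedure, exports per-target DICOM treatment datasets, and evaluates
    retrieved injection positions by signed along-contour distance to the
    border zone and perpendicular depth. Ships a synthetic left-ventricle
    phantom generator with analytic ground truth, and the two-sample
    summary-statistics tests used for group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti,
    mgcv,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
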