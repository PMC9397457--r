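Package: jcsuncert
Title: Uncertainty Propagation in Knee Joint Angle Computation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytical first-order propagation of measurement uncertainty in
    knee joint kinematics. Describes the relative shank-to-thigh rotation by
    its attitude vector (rotation angle and unit rotation axis) projected
    non-orthogonally on the joint coordinate system axes, reduces the pose to
    seven independent parameters, and propagates intrinsic (rotation angle
    and axis) and extrinsic (joint-axis orientation) input uncertainties to
    the three clinical joint angles via closed-form sensitivities. Includes a
    Monte-Carlo verification oracle, a synthetic multi-session gait
    generator, inter- and intra-session RMSD variability analysis, CSV/JSON
    interfaces and a command-line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
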