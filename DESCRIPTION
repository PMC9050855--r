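Package: flowunwrap
Title: Velocity Anti-Aliasing for 4D-Flow MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation, detection, and correction of velocity aliasing
    (phase wrapping) in time-resolved three-directional phase-contrast MRI
    velocity fields. Provides a pulsatile Poiseuille tube/U-bend phantom
    generator with venc-proportional noise, an exact venc-reduction wrap
    simulator with ground-truth masks, a conventional spatio-temporal
    phase-jump unwrapping algorithm, a trainable dense-block U-Net voxel
    classifier implemented with 'RcppArmadillo', mask-overlap metrics (Dice
    with epsilon stabilisation, Hausdorff distance in mm), plane-based flow
    quantification, and Bland-Altman agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
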