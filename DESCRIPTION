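Package: wallshear
Title: Aortic Wall Shear Stress Estimation from 4D-Flow-Style Velocity Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates aortic wall shear stress (WSS) from 4D Flow MRI-like
    velocity data. A structured quadrilateral vessel template is registered to a
    target surface with coherent point drift, unwrapped into 2D "flatmaps" of
    coordinates and near-wall velocity sheets, and fed to a patch-based
    convolutional estimator trained with a composite MAE + SSIM loss. Includes a
    classical parabolic-fitting baseline, an analytic pulsatile tube-flow
    generator with closed-form wall shear stress for training and validation,
    synthetic-MRI voxelization with venc-scaled noise, and the standard
    hemodynamic evaluation suite (TAWSS, OSI, MAE, relative error, Pearson
    correlation, ICC(A,1), Bland-Altman, linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml,
    optparse
Config/testthat/edition: 3
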