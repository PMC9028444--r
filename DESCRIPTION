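Package: eimnet
Title: Reference-Free Electrical Impedance Tomography with Electrical
    Impedance Map Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Absolute (reference-free) electrical impedance tomography on a
    circular 16-electrode domain. Provides a complete-electrode-model finite
    element forward solver, a randomized conductivity-phantom generator, the
    16x16 electrical impedance map (EIM) representation with its diagonal-shift
    rotation structure, measurement-noise and alpha-blending data augmentation,
    a rotationally weight-shared convolutional reconstruction network trained
    with a composite MSLE/total-variation/weight-decay loss, a regularized
    Gauss-Newton reconstruction baseline, and modified GREIT figures of merit
    (amplitude response, position error, ringing) for absolute images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
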