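Package: icrlab
Title: Digital Laboratory for Instantaneous Centers of Rotation of Rigid Bodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An in-silico laboratory for studying instantaneous centers and
    axes of rotation (ICR) of rigid bodies, motivated by temporomandibular
    joint (hinge-axis) kinematics. Registers the finite helical (screw) axis
    between two poses of a rigid body, predicts analytically how a
    translational component displaces the registered axis (the error-caused
    displacement ratio, EcD = 1/(2 sin(alpha/2)) for translation
    perpendicular to the axis), and quantifies the error tolerance of
    articulation systems by simulating deliberately misplaced rotation axes
    (parallel, perpendicular and circular error types, summarized by the
    axis-error-caused final-error ratio AEcFE). Includes a deterministic
    generator of dental-arch-like synthetic meshes, STL/OBJ readers and
    writers, tidy experiment pipelines returning tibbles, ggplot2 plots, and
    a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
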