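Package: sternometry
Title: Automated Osteometry and Sex Estimation of the Human Sternum
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments manubrium and sternal-body silhouettes from 2D
    computed-tomography projection images, locates osteometric landmarks,
    and computes the five standard sternal measurements (manubrium length
    and width, sternal body length, and two corpus widths) together with
    the sternal index, sternal area and combined length.  Ships nine
    published discriminant functions for sex estimation from these
    measurements, supports refitting two-group discriminant functions with
    leave-one-out validation, and quantifies manual-versus-automatic
    method agreement.  A synthetic phantom generator with exact
    ground-truth landmarks makes every stage testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    MASS,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
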