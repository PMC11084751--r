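Package: cervimetrics
Title: Sagittal Cervical Spine Mensuration and Reliability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the 18 rotational and translational sagittal alignment
    variables of the cervical spine (absolute and relative rotation angles by
    the posterior tangent method, segmental Cobb angles, segmental and global
    translations, and the atlas plane angle) from digitized vertebral landmark
    coordinates on lateral radiographs. Provides repeated-measures reliability
    statistics (intraclass correlation, root mean squared error, regression
    R-squared with effect-size and cleanliness bands), a parametric synthetic
    spine and annotation-noise simulator with exact ground truth for
    validation studies, and a pipeline reproducing rater-vs-rater and
    algorithm-vs-rater agreement experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
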