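Package: iczone
Title: Modeling the Individual Convenient Zone of the Upper Limb
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models a person's individual convenient zone (ICZ): the space
    reachable by the upper limb, annotated at every point with the maximum
    upward force the person can exert there.  Builds interpolated strength
    fields from laboratory force point clouds in a body-centered cylindrical
    frame, extracts nested constant-strength layers, rescales limit forces to
    allowable working forces, and matches a quickly measured five-feature
    profile (four strength values and the anterior reach) against a repository
    of fully measured subjects using min-max normalization and a mean absolute
    difference similarity statistic.  Product and furniture layouts can be
    assessed point by point for reachability and force adequacy, and layers
    exported as ASCII OBJ/STL meshes for CAD.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
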