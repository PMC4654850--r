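Package: EyeSphere
Title: Localization of Focal Retinal Injections from Orthogonal Images of the Intact Eye
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the position (and optionally the area) of a focal dye
    injection on the retina from two orthogonal bright-field images of the
    intact eye, without dissecting and flattening the tissue. The eye is
    modelled as an ellipsoid with a rim opening; user-supplied wire-frame
    alignment parameters (rotations, translation, semi-axes, rim angle) define
    each view, a pixel mark in each view is back-projected to a line and the
    two lines are triangulated onto the eye surface. Positions are reported as
    fractional coordinates along the nasotemporal and dorsoventral axes in a
    wedge coordinate system of circular arcs through the axis poles, and in
    spherical polar coordinates for flat export. Injection area is estimated by
    CIELAB chroma-distance thresholding, ray/ellipsoid intersection and an
    alpha-shape in an equal-area projection. A seeded synthetic-scene generator
    with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    jsonlite,
    png,
    jpeg,
    farver,
    deldir
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
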