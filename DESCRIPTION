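Package: coneclear
Title: Collision Clearance Prediction for Cone-Based Stereotactic Radiosurgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts mechanical clearance between a stereotactic conical
    collimator and treatment setup hardware (couch extensions, positioning
    arrays) for arbitrary couch and gantry angle combinations. Hardware outer
    contours, read from DICOM RT structure sets or built from synthetic
    fixtures, are transformed into the beam's-eye-view (collimator) frame by
    the IEC-style rigid rotations of an isocentric linac; the signed clearance
    between the cone solid and the nearest contour point is evaluated at every
    gantry angle of an arc, and maximal collision-free gantry sub-arcs are
    reported under configurable detection and safety margins.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    optparse,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
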