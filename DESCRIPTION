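Package: wbi
Title: Walking Balance Index from Force-Plate and Kinematic Gait Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies human walking balance from treadmill gait trials.
    From synchronized ground-reaction-force/moment records and body-segment
    centroid trajectories it computes 14 instantaneous balance metrics
    (center of pressure, its velocity, center-of-mass position and
    acceleration, the centroidal-moment-pivot offset, the margin of
    stability and trunk angular acceleration), segments them into gait
    cycles, reduces each stride to time-domain features (RMS, variance,
    range), selects features that separate a balanced from a perturbed
    condition with a normality- and homoscedasticity-gated two-sample test,
    and combines the selected features into a single eigenvalue-weighted
    principal-component score per stride, the Walking Balance Index (WBI).
    Includes a seeded synthetic-gait generator for the balanced and
    perturbed treadmill conditions the method assumes, text-format readers
    and writers, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
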