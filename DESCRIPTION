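Package: sprintsim
Title: Data-Tracking and Predictive Optimal-Control Simulation of Accelerative Sprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A planar muscle/torque-driven multibody model of accelerative
    sprinting with implicit skeletal, contraction and activation dynamics,
    smooth Hunt-Crossley foot-ground contact, metatarsophalangeal springs and
    aerodynamic drag; a flipped Legendre-Gauss-Radau direct-collocation
    transcriber with a sparse primal-dual interior-point solver; data-tracking
    simulations against (synthetic, dynamically consistent) two-step sprint
    datasets; a suite of free-moment predictive simulations that minimise the
    time horizon while tracking selected net joint moments; and the outcome
    measures used to compare them (average horizontal external power,
    stance-phase impulses, touchdown and take-off kinematics, peak net moments
    and the front-side/back-side trunk-to-thigh classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    signal,
    splines,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
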