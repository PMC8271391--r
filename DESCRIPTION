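Package: imugait
Title: Virtual Inertial Sensor Simulation and Neural-Network Gait Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates virtual inertial measurement unit (IMU) signals from
    rigid-body segment kinematics using quaternion algebra, augments them
    across a library of sensor-to-segment placements, and regresses
    three-dimensional lower-limb joint angles and moments from the simulated
    signals with three neural-network families (multilayer perceptron, long
    short-term memory, convolutional network on image-encoded signals).
    Includes a parametric synthetic gait cohort generator, signal
    preprocessing (zero-lag Butterworth filtering, cross-correlation
    synchronisation, time normalisation, confidence-based sample filtering),
    three network-specific tensor layouts, hyperband hyperparameter search,
    and leave-one-subject-out evaluation with range-normalised RMSE and
    correlation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
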