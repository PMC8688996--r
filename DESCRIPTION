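Package: swimphase
Title: Phase-Based Swimming Performance Evaluation from a Sacrum-Worn IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate swimming performance from a single sacrum-worn
    inertial measurement unit (IMU). Raw six-axis inertial signals are
    calibrated, fused into a quaternion orientation trace with a
    gradient-descent complementary filter, and expressed in a pool-fixed
    global frame. Each 25 m lap is segmented into wall push-off, glide,
    stroke-preparation and swimming phases; stroke cycles are separated from
    angular-velocity peaks; and a catalogue of phase-based kinematic
    micro-variables (propulsion, posture, efficiency and duration/rate
    categories) is extracted. Eight velocity and time goal metrics are
    computed from a tethered-speedometer reference trace (with parallax
    correction), and estimated from the micro-variables via variance
    inflation factor filtering, LASSO variable selection with relative
    weights, and leave-one-out cross-validated LASSO regression. A
    ground-truthed synthetic lap simulator supports testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
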