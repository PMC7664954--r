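Package: zuptr
Title: Zero-Velocity Update Detection and Inertial Motion Tracking
Version: 0.1.0
Authors@R:
    person("zuptr", "developers", email = "zuptr@example.org", role = c("aut", "cre"))
Description: Tools for tracking human translational motion from body-worn
    inertial measurement units (IMUs). Implements zero-velocity detection with
    fixed-threshold detectors (SHOE, ARED) and learned classifiers (logistic
    regression, support vector machine, random forest, LSTM sequence models),
    zero-velocity-gated double integration with per-segment linear drift
    removal, warm-started LSTM displacement regressors whose initial weights
    encode Euler integration, a stacked network that detects stationary
    periods and regresses displacement jointly, trial-level error metrics
    (per-axis RMSE/MAE/R-squared, 3D ATE/MAE), and a synthetic human-motion
    IMU simulator so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
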