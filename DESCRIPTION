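Package: baroimu
Title: Baro-Inertial Sensor Fusion for Vertical Velocity and Height Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks the height and vertical velocity of a moving body at 50 Hz
    from a baro-IMU (tri-axial gyroscope, tri-axial accelerometer and barometric
    altimeter). A quaternion-based extended Kalman filter with accelerometer-bias
    self-compensation and innovation-based vector selection estimates attitude;
    the sensed specific force is rotated into the navigation frame and
    compensated for gravity; pressure is converted to relative altitude,
    detrended by rest-period bias capture and conditioned by a moving-average
    filter optionally cascaded with a first-order whitening filter; a critically
    damped two-state complementary filter fuses vertical linear acceleration
    with conditioned pressure altitude. Includes a scenario simulator
    (no-motion, free fall, forced circular motion, squatting) with correlated
    barometric noise and 1 Pa quantization, RMSE-based evaluation against
    analytic references, and command-line entry points.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
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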