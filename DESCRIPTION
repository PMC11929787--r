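Package: suncompass
Title: Time-Compensated Insect Celestial Compass Models and Navigation
    Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models of how insects could keep a sun compass useful all day
    long.  Implements clock-driven predictions of the solar azimuth (an
    hour-angle model recentred on solar noon, and a complete model using
    annual solar declination and latitude estimated from geomagnetic
    inclination), the trigonometric neural circuit (MeTu2, TuBu1, ER4m
    populations) that fuses the predicted and observed sun position into a
    geocentric heading signal, and a complex-vector central-complex model
    for path integration and steering.  Includes a NOAA-style solar
    ephemeris for ground truth, a circadian day-length estimator driven by
    skylight irradiance, and agent-based simulations of central-place
    foraging on a plane and long-range migration on a sphere using
    quaternion kinematics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
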