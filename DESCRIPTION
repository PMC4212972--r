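Package: camtrapemit
Title: Functional Analysis of Camera-Trap Acoustic and Infrared Emissions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing whether the acoustic and infrared emissions
    of camera traps are perceptible to wildlife. Treats one-third-octave band
    sound spectra as functional data: bootstrap confidence envelopes for mean
    spectral curves, two-sample permutation t-max tests with per-frequency
    critical curves, and false-discovery-rate corrected pairwise model
    contrasts. Also provides species hearing-range overlap and audiogram
    audibility margins, ultrasonic detection-range summaries, infrared
    peak-wavelength summaries with t-based confidence intervals, spherical
    spreading-loss attenuation, and a seeded synthetic-data generator that
    emulates replicate spectral measurements for testing and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
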