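Package: mtsurround
Title: Adaptive Surround Modulation in a Two-Stage V1-MT Motion Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Rate-based simulator of a two-stage model of primate motion
    processing in which direction-selective middle temporal (MT) neurons
    carry an adaptive extra-classical surround. Motion-energy complex V1
    units, end-stopped units, and contrast-sensitive oriented
    difference-of-Gaussians (ECRF) units feed a recurrent MT sheet whose
    surround switches between facilitatory and antagonistic as a sigmoidal
    function of local image contrast and motion discontinuity. Ships a
    procedural stimulus generator (crossing bars, occluded plaids, single
    bars, drifting gratings) with ground-truth masks, analysis metrics
    (direction decoding, disambiguation latency, terminator selectivity,
    pattern/component classification), and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
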