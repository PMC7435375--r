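Package: drowsefis
Title: Fuzzy Drowsiness Estimation from Facial-State Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for behavioural driver-drowsiness monitoring from
    per-frame facial measurements. Reads and writes per-frame facial-state time
    series (eyelid gap, mouth aspect ratio, or pre-binarized eye/mouth states),
    performs a one-minute personalized calibration of open-eye and open-mouth
    references (top-5 percent averaging, 20 percent eye-closure rule, mouth
    aspect ratio threshold), computes sliding-window drowsiness indicators
    (PERCLOS, eye closing duration, average mouth opening time) each second over
    a one-minute window, and maps them through a Mamdani fuzzy inference system
    with singleton consequents and minimum-of-maximum defuzzification to a
    three-level drowsiness state (Normal, Drowsy, Severe). Includes a geometric
    68-point facial-landmark frontend for frame sequences, a seeded synthetic
    blink/yawn stream simulator with ground-truth labels, and segment-level
    confusion-matrix evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
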