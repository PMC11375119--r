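Package: nullreach
Title: Wrist Muscle-to-Force Null-Space Reaching Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and closed-loop simulation pipeline for isometric
    wrist myoelectric interfaces that expose the muscle-to-force null-space as
    a control signal. Implements EMG envelope extraction (Butterworth high-pass,
    rectification, low-pass), ordinary-least-squares estimation of the 2x4
    pulling matrix mapping four wrist-muscle envelopes to planar force, the
    scaled and co-contraction-aligned null-space coordinate system with its
    non-negative reachable cone, deterministic simulation of null-space target
    reaching (NSTR) and concurrent target reaching (CTR) paradigms with the
    adaptive target-progression rule, and the behavioural trajectory metrics
    (motion efficiency, correction counting, force RMS, reaching range, motion
    concurrency phases). A synthetic-data module generates muscle geometries,
    calibration sessions and closed-loop sessions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
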