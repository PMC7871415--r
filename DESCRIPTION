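Package: bleachr
Title: Photobleaching Correction for Fluorescence Time-Lapse Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compensates photobleaching in single-channel fluorescence
    time-lapse sequences (2D frames or 3D z-stacks per time point) with
    three algorithms: per-frame simple ratio against the first frame with
    background subtraction, two-pass single-exponential fitting of the
    per-time-point mean series, and histogram matching of every time point
    to the first frame via discrete CDF inversion. Includes a multi-page
    TIFF reader/writer (plain and ImageJ-hyperstack dialects), a synthetic
    bleached-stack simulator with known ground truth for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, optparse
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
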