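Package: romocap
Title: Marker-Based Motion-Capture Analysis of Spinal and Shoulder Range of Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for marker-based optoelectronic motion-capture
    assessments of spinal and shoulder active range of motion (ROM). Reads 3D
    marker trajectories from C3D, TRC or a documented wide-CSV dialect, applies
    gap interpolation and zero-phase low-pass Butterworth filtering, constructs
    a pelvis-anchored anatomical reference frame, computes shoulder and spinal
    segment angles, segments repetitions by angular extrema to extract
    per-repetition ROM and task duration, and reproduces a repeated-measures
    statistical workflow (Shapiro-Wilk and Levene assumption checks, paired and
    mixed repeated-measures ANOVA with Holm-corrected post hocs and Cohen's d).
    A forward-kinematic synthetic-trial generator with known ground truth makes
    every stage testable without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
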