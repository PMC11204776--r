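Package: pivotshift
Title: Quantitative Analysis of Smartphone-Gyroscope Pivot-Shift Knee Exams
Version: 0.1.0
Authors@R:
    person("PSM", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate, ingest and analyse tri-axial angular-velocity
    recordings of the pivot-shift knee examination captured with a smartphone
    gyroscope (100 Hz, 5 s). Provides peak detection and maneuver segmentation
    of the X-axis signal, extraction of the joint-reduction ("pivot") segment,
    morphological feature computation, intra- and interobserver reliability via
    intraclass correlation coefficients computed from ANOVA mean squares,
    KT-1000-based laxity grading on the 0-3 "Del Parque" scale, speed-based
    maneuver-class binning, and a two-stage machine-learning pipeline (maneuver
    class, then laxity grade within class) with logistic-regression, support
    vector machine, decision-tree and random-forest back ends. Includes a
    deterministic synthetic-cohort generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet,
    quadprog,
    optparse
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
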