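Package: cyclemetrics
Title: Balance, Proprioception and Body-Composition Analysis Across the Menstrual Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for a repeated-measures study design in which athletes are
    tested many times across one menstrual cycle. Implements marker-less
    joint-position-sense scoring from frontal-plane silhouette images (Canny
    edges, limb-midpoint regression lines, angle deviations from a 90/90/0
    target pose), perturbation-response balance metrics (threshold, settling
    time, path distance, rectified area) from 50 Hz platform displacement
    traces, cycle-day allocation from recorded menses onsets, a biquadratic
    random-coefficient linear mixed model fitted by restricted maximum
    likelihood with a combined F-test of all time-dependent terms, and a
    Pearson correlation screen between modality pairs. A synthetic-data
    module generates silhouettes, damped-oscillation perturbation traces and
    longitudinal study tables with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    EBImage,
    withr,
    optparse
Config/testthat/edition: 3
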