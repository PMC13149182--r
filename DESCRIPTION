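Package: cortqct
Title: Vertebral Cortical Bone Morphometry and QCT Osteoporosis Discrimination
Version: 0.1.0
Authors@R: person("cortqct", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the cortical shell of an L1-like vertebral body on CT
    and evaluates the resulting parameters as osteoporosis discriminators.
    Provides a digital CT phantom generator with analytic ground truth, a
    threshold-plus-morphology cortical/trabecular segmentation surrogate,
    ray-cast cortical thickness together with area, volume and density
    morphometry, a QCT-style elliptical-ROI volumetric bone mineral density
    (vBMD) measurement with the standard 80/120 mg/cm3 classification, and
    the cohort statistics used in this field: Levene's test, one-way ANOVA
    (raw and summary-statistic forms) with LSD post hoc, empirical ROC with
    Youden cutoff, binormal-mixture AUC, and the paired DeLong test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
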