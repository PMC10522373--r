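Package: methnoise
Title: Fail-Tests of DNA Methylation Clocks and an Epigenetic Noise Barometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits elastic-net DNA-methylation age clocks (probe-removal and
    retraining experiments, weight-rank versus age-signal regressions, binned
    correlation checks, cohort residual summaries) and implements a
    complementary measurement of biological age from epigenetic noise: probes
    whose mean methylation is age-invariant but whose dispersion grows with age
    are selected by three procedures, per-sample noise is scored as the
    young-normalized sum of absolute deviations from the probe means, and
    binned summed-standard-deviation curves are inverted through a polynomial
    fit to map noise onto biological age. Includes an age-structured synthetic
    450K-array cohort generator with planted probe classes so every stage is
    testable at desk scale, plus readers for GEO series-matrix and CSV beta
    matrices.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
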