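Package: somamat
Title: Somatic Maturation Assessment and Method-Agreement Toolkit for Youth Athletes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Non-invasive somatic maturation assessment for adolescent athletes:
    maturity offset and age at peak height velocity from sex-specific
    anthropometric regressions, predicted adult height from age-indexed
    coefficient tables in the Khamis-Roche style, percent of adult height, and
    maturity status/timing classification. Includes a pinhole-geometry stature
    estimator for wall-calibrated photographs, a full method-agreement battery
    (paired mean difference, two-way absolute-agreement intraclass correlation
    with F-based confidence intervals, technical error of measurement,
    classification cross-tabulation with Cohen's kappa), a seeded synthetic
    cohort generator built on the Preece-Baines model 1 growth curve, CSV/JSON
    readers and writers, individual and team reports, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
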