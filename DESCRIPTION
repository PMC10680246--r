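Package: wit2sim
Title: Weight-Based Basal-Bolus Insulin Titration Engine and In-Silico
    Inpatient Trial Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic implementation of the WIT2 weight-based
    basal-bolus insulin initiation and titration algorithm for hospitalized
    patients with type 2 diabetes, in its two variants (basal:bolus 1:1.5
    started at 0.5 units/kg/day and 1:1 started at 0.4 units/kg/day), with
    treat-to-target daily titration, hypoglycemia classification and
    handling, and the accompanying standardized dietary prescription. The
    dosing engine is embedded in an in-silico trial simulator: a synthetic
    virtual-patient cohort with heterogeneous first-order glucose responses
    to basal and bolus dosing is run through the full two-arm inpatient
    trial design, and time-to-target, final-dose, and hypoglycemia
    endpoints are extracted and compared with two-sample summary t-tests
    and chi-square proportion tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
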