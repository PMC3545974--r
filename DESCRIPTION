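Package: osteosim
Title: Patient-Level Microsimulation of Osteoporosis Treatment
    Cost-Effectiveness
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A patient-level Monte Carlo microsimulation of osteoporosis
    treatment for severe postmenopausal (PMO) and glucocorticoid-induced
    (GIOP) cohorts.  Simulates hip, clinical vertebral and wrist fractures,
    natural and fracture-related excess mortality, drug, monitoring and
    fracture costs, and multiplicative health-utility accounting in six-month
    cycles, for teriparatide, oral bisphosphonate and no-treatment arms under
    common random numbers.  Produces lifetime discounted costs and QALYs,
    incremental cost-effectiveness ratios with dominance handling, fractures
    avoided per 1,000 patients, one-way sensitivity (tornado) tables, and
    probabilistic sensitivity analyses with cost-effectiveness acceptability
    curves.  Ships a fully documented default parameter bundle in which
    tables not available from the primary sources are generated placeholders,
    flagged as such and swappable for user-supplied data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
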