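Package: strokeCEA
Title: Cost-Effectiveness of Argatroban in Acute Ischemic Stroke with
    Early Neurological Deterioration
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort state-transition model for the
    cost-effectiveness of intravenous argatroban added to standard therapy in
    Chinese patients with acute ischemic stroke and early neurological
    deterioration.  Health states are modified Rankin Scale (mRS) categories
    0-6; a 3-month decision tree seeds a 119-cycle (30-year) quarterly Markov
    model with stroke recurrence, recurrence case fatality, and hazard-ratio
    adjusted background mortality.  Provides deterministic base-case and
    scenario analyses, one-way (tornado) sensitivity analysis, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, moment
    matching of beta/gamma/lognormal/Dirichlet parameter distributions from
    published point estimates and ranges, and synthetic two-arm trial data
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
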