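Package: gtbias
Title: Guarantee-Time Bias in Pharmacoepidemiologic Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying guarantee-time (immortal time) bias in
    cohort studies of cumulative drug exposure. Provides a discrete-time
    cohort simulator with time-varying cumulative dose, three competing
    hazard-ratio estimators (time-fixed Cox regression, time-dependent Cox
    regression with counting-process data, and landmark analysis), the
    closed-form conditional densities that justify landmark comparisons
    under the null, and a Monte-Carlo harness that aggregates type I error,
    power, bias and mean squared error across replications.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
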