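Package: sbarisk
Title: Skilled Birth Attendance Risk Modelling for Maternity Waiting Home Planning
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a woman-specific model of the probability that a
    skilled birth attendant (SBA) is present when the active phase of labour
    begins, P(SBA) = 1 - Gk(t) F(d), where F is the cumulative distribution
    of labour onset relative to the expected due date and Gk the
    parity-specific cumulative distribution of the latent phase of labour.
    Provides Gaussian kernel density estimation of both distributions on
    truncated supports, calibrated truncated-normal-mixture surrogates
    matched to published cohort summary statistics, seeded synthetic cohort
    generators, bootstrap percentile confidence intervals with running-SD
    convergence monitoring, conservative risk tables over access-time
    intervals and maternity-waiting-home (MWH) move-date scenarios, and a
    threshold rule recommending the least burdensome adequate move date.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
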