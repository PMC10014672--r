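Package: tacecua
Title: Markov Cohort Cost-Utility Analysis of Chemoembolization Strategies
    in Hepatocellular Carcinoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Cost-utility analysis of drug-eluting microsphere (DEM-TACE)
    versus conventional (C-TACE) transarterial chemoembolization for
    unresectable hepatocellular carcinoma, built as a reusable pipeline:
    seeded simulation of matched patient cohorts from an exponential
    illness-death process with skewed two-part state costs, nonparametric
    multi-state estimation (Kaplan-Meier and Aalen-Johansen transition
    probabilities), a three-state Markov cohort engine accumulating
    discounted costs and quality-adjusted life years over a lifetime
    horizon, incremental cost-utility ratios with dominance handling and
    net monetary benefit, and probabilistic sensitivity analysis producing
    cost-effectiveness planes and acceptability curves.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
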