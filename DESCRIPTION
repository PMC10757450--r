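Package: stopsignal
Title: Simulation and Analysis of Stop-Signal Task Inhibition Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying reactive and proactive motor inhibition with
    the stop-signal task. Provides a seeded independent horse-race cohort
    simulator with staircase stop-signal-delay tracking, trial-table
    preprocessing (outlier trimming, reaction-time-limit handling, accuracy),
    stop-signal reaction time (SSRT) estimation by the integration method with
    race-model assumption checks, proactive-inhibition ("context effect")
    analysis via exact one- and two-sided two-sample Kolmogorov-Smirnov tests
    at the individual and population level, and a balanced mixed-design
    (split-plot) ANOVA engine with Bonferroni post hocs, effect sizes, default
    Jeffreys-Zellner-Siow Bayes factors and chi-square procedures for
    context-effect frequency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
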