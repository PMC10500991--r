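Package: cppreserve
Title: EEG Decision Signals, Shifted-Wald Diffusion Fits, and Enrichment
    Moderation for Response-Speed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking single-trial EEG decision signals to visual
    response speed in aging cohorts: a synthetic cohort generator with a
    one-boundary diffusion behavioural model and planted centroparietal
    positivity (CPP), N2c and left-hemisphere beta components; FIR-based
    preprocessing with amplitude- and RT-based trial exclusion; ERP and
    temporal-spectral-evolution metric extraction (N2c latency/amplitude,
    CPP onset via running t tests, CPP build-up rate and amplitude, beta
    latency/slope/amplitude); per-subject detection drift-diffusion fits by
    G-square minimisation with Powell's method over RT quantile bins; cohort
    statistics (hierarchical regression with R-squared change, moderation
    with conditional effects, bootstrapped mediation, one-way ANOVA with
    partial eta-squared, JZS Bayes-factor t tests); and trial-subsampling
    reliability analyses with a task-time budget calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
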